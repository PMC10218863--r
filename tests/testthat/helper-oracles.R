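# Independent oracles, coded apart from the package implementation.

# maximum number of nested base pairs (WC + GU, min hairpin h) by a
# bottom-up interval DP written independently of the package's C++ engine
oracle_max_pairs <- function(seq, h = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  n <- length(ch)
  if (n == 0L) return(0L)
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  M <- matrix(0L, n, n)
  if (n >= h + 2L) for (l in (h + 2L):n) for (i in seq_len(n - l + 1L)) {
    j <- i + l - 1L
    best <- M[i, j - 1L]  # j unpaired (note: different split than the engine)
    for (k in i:(j - h - 1L)) {
      if (!ok(ch[k], ch[j])) next
      left <- if (k > i) M[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
      best <- max(best, left + inner + 1L)
    }
    M[i, j] <- best
  }
  M[1L, n]
}

# exhaustive enumeration of every nested structure (tiny n only)
oracle_enum_max_pairs <- function(seq, h = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < h + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + h + 1L):j) {
      if (ok(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(ch) == 0L) 0L else rec(1L, length(ch))
}

# validity of a dot-bracket string for a sequence under the engine's rules
oracle_structure_valid <- function(seq, db, h = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  st <- integer(0)
  for (i in seq_along(ch)) {
    c_ <- substr(db, i, i)
    if (c_ == "(") st <- c(st, i)
    else if (c_ == ")") {
      if (!length(st)) return(FALSE)
      j <- st[length(st)]
      st <- st[-length(st)]
      if (i - j - 1L < h) return(FALSE)
      if (!ok(ch[j], ch[i])) return(FALSE)
    }
  }
  length(st) == 0L
}

count_pairs <- function(db) sum(strsplit(db, "")[[1L]] == "(")

# per-class precision/recall/F1 and multiclass MCC via indicator-vector
# correlation (covariance formulation), built from a counts matrix
oracle_scores <- function(cm) {
  k <- nrow(cm)
  n <- sum(cm)
  true <- integer(0); pred <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    true <- c(true, rep(i, cm[i, j]))
    pred <- c(pred, rep(j, cm[i, j]))
  }
  X <- matrix(0, n, k); Y <- matrix(0, n, k)
  X[cbind(seq_len(n), pred)] <- 1
  Y[cbind(seq_len(n), true)] <- 1
  cov2 <- function(A, B) sum(diag(crossprod(scale(A, scale = FALSE),
                                            scale(B, scale = FALSE))))
  den <- sqrt(cov2(X, X)) * sqrt(cov2(Y, Y))
  mcc <- if (den == 0) 0 else cov2(X, Y) / den
  prec <- rec <- f1 <- numeric(k)
  for (c_ in seq_len(k)) {
    tp <- sum(pred == c_ & true == c_)
    prec[c_] <- if (sum(pred == c_) == 0) 0 else tp / sum(pred == c_)
    rec[c_] <- if (sum(true == c_) == 0) 0 else tp / sum(true == c_)
    f1[c_] <- if (prec[c_] + rec[c_] == 0) 0
              else 2 * prec[c_] * rec[c_] / (prec[c_] + rec[c_])
  }
  list(precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

oracle_binary_mcc <- function(tp, fn, fp, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

random_confusion <- function(k, max_count = 20L) {
  matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
}

# count of (neighborhood, neighborhood, distance) triples in a graph,
# enumerated with igraph shortest paths
oracle_nspdk_total <- function(n_vertices, edges_from, edges_to,
                               max_radius = 1L, max_distance = 4L) {
  g <- igraph::make_empty_graph(n = n_vertices, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  d <- igraph::distances(g)
  total <- 0L
  for (u in seq_len(n_vertices)) for (v in u:n_vertices)
    if (is.finite(d[u, v]) && d[u, v] <= max_distance)
      total <- total + (max_radius + 1L)
  total
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

make_tiny_set <- function() {
  NcRNASet(id = c("r1", "r2", "r3"),
           sequence = c("GGGGAAAACCCC", "ACGUACGUACGUACG", "AAAAAAAAAAAAAAA"),
           label = c("rRNA", "tRNA", "lncRNA"))
}
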