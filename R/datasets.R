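#' Read a labeled FASTA file
#'
#' Sequences come from a FASTA file; labels from a tab-separated sidecar
#' with columns \code{id}, \code{label} and optionally \code{subtype}.
#' Sequences are normalized to uppercase; DNA \code{T} is preserved (the
#' sequence vocabulary carries both \code{T} and \code{U}).
#'
#' @param fasta path to the FASTA file.
#' @param labels path to the label TSV.
#' @return an \linkS4class{NcRNASet}.
#' @export
readLabeledFasta <- function(fasta, labels) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id '%s' in FASTA", ids[duplicated(ids)][1L]))
  lab <- read.delim(labels, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(lab)))
    stop("label file must have columns 'id' and 'label'")
  if (anyDuplicated(lab$id))
    stop(sprintf("duplicate id '%s' in label file",
                 lab$id[duplicated(lab$id)][1L]))
  missing <- setdiff(ids, lab$id)
  if (length(missing))
    stop(sprintf("missing label for id(s): %s",
                 paste(head(missing, 5L), collapse = ", ")))
  m <- match(ids, lab$id)
  NcRNASet(id = ids, sequence = as.character(seqs),
           label = lab$label[m],
           subtype = if ("subtype" %in% names(lab)) lab$subtype[m]
                     else NA_character_)
}

#' Write an NcRNASet as FASTA plus label TSV
#'
#' @param x an \linkS4class{NcRNASet}.
#' @param fasta output FASTA path.
#' @param labels output label TSV path.
#' @return invisibly, the FASTA path.
#' @export
writeLabeledFasta <- function(x, fasta, labels) {
  set <- Biostrings::BStringSet(setNames(x@sequence, x@id))
  Biostrings::writeXStringSet(set, fasta)
  write.table(data.frame(id = x@id, label = x@label, subtype = x@subtype),
              labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' Length filter
#'
#' Keeps records whose length lies in \code{[min, max]} (both boundaries
#' inclusive); order is preserved.
#'
#' @param records an \linkS4class{NcRNASet}.
#' @param min,max length bounds in nt.
#' @return the filtered \linkS4class{NcRNASet}.
#' @export
lengthFilter <- function(records, min = 15L, max = 11922L) {
  len <- seqLengths(records)
  records[len >= min & len <= max]
}

#' miRNA length class
#'
#' Mature/precursor assignment by length: at most 30 nt is mature, at least
#' 40 nt is precursor, 31-39 nt falls in the gap and is excluded.
#'
#' @param length sequence length(s) in nt.
#' @return character vector over \{"mature", "precursor", "excluded"\}.
#' @examples
#' assignMirnaLengthClass(c(22, 35, 100))
#' @export
assignMirnaLengthClass <- function(length) {
  stopifnot(all(length >= 1L))
  ifelse(length <= 30L, "mature",
         ifelse(length >= 40L, "precursor", "excluded"))
}

.kmer_set <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

#' Pairwise sequence identity
#'
#' Identity of two sequences as matches over the length of the shorter
#' sequence, assessed by fitting the shorter sequence into the longer one
#' with an overlap alignment.
#'
#' @param a,b sequences.
#' @return identity in [0, 1].
#' @export
sequenceIdentity <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(b) == 0L) return(0)
  al <- Biostrings::pairwiseAlignment(
    pattern = b, subject = a, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "RNA"),
    gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(al) / nchar(b)
}

#' Greedy identity-based redundancy reduction
#'
#' Greedy clustering in the CD-HIT style: records are visited longest-first
#' (ties broken by id); a record joins the first existing cluster whose
#' representative exceeds the identity threshold (identity = matches over
#' the shorter length, with a shared \code{wordLength}-mer prefilter before
#' the alignment), otherwise it founds a new cluster.  Representatives are
#' returned in visiting order.
#'
#' @param records an \linkS4class{NcRNASet}.
#' @param identity identity threshold (default 0.90; similarities strictly
#'   above it are redundant).
#' @param wordLength k-mer length of the prefilter (default 7).
#' @return the \linkS4class{NcRNASet} of cluster representatives.
#' @export
clusterReduce <- function(records, identity = 0.90, wordLength = 7L) {
  if (length(records) == 0L) stop("records must be non-empty")
  ord <- order(-nchar(records@sequence), records@id)
  reps <- integer(0)
  rep_words <- list()
  seqs <- chartr("T", "U", records@sequence)
  for (i in ord) {
    w <- .kmer_set(seqs[i], wordLength)
    joined <- FALSE
    for (r in seq_along(reps)) {
      if (!length(intersect(w, rep_words[[r]]))) next
      if (sequenceIdentity(seqs[i], seqs[reps[r]]) > identity) {
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      rep_words[[length(reps)]] <- w
    }
  }
  records[reps]
}

#' Maximum identity of records against a reference set
#'
#' @param records an \linkS4class{NcRNASet}.
#' @param reference an \linkS4class{NcRNASet} of reference (e.g. training)
#'   sequences.
#' @param wordLength k-mer prefilter length.
#' @return numeric vector: for each record, the maximum identity to any
#'   reference sequence (0 when the prefilter excludes all).
#' @export
maxIdentityTo <- function(records, reference, wordLength = 7L) {
  ref_seqs <- chartr("T", "U", reference@sequence)
  ref_words <- lapply(ref_seqs, .kmer_set, k = wordLength)
  qry <- chartr("T", "U", records@sequence)
  vapply(qry, function(s) {
    w <- .kmer_set(s, wordLength)
    best <- 0
    for (r in seq_along(ref_seqs)) {
      if (!length(intersect(w, ref_words[[r]]))) next
      best <- max(best, sequenceIdentity(s, ref_seqs[r]))
      if (best >= 1) break
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

#' Balanced train/validation/test split
#'
#' Per class: \code{testPerClass} records go to the test partition and the
#' remaining pool is split 90/10 into train and validation.  Where subtypes
#' exist the draws are balanced per subtype (equal draw per subtype, the
#' remainder distributed deterministically over the subtype order).  A class
#' with fewer than \code{perClassTotal} records keeps all of them, with a
#' warning.
#'
#' @param records an \linkS4class{NcRNASet}.
#' @param perClassTotal target records per class (e.g. 10000).
#' @param testPerClass test records per class (e.g. 1000).
#' @param seed RNG seed.
#' @param trainFraction fraction of the non-test pool used for training.
#' @return list with \linkS4class{NcRNASet} elements \code{train},
#'   \code{validation}, \code{test} and a \code{counts} data.frame.
#' @export
makeSplit <- function(records, perClassTotal, testPerClass, seed = 1L,
                      trainFraction = 0.9) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  classes <- sort(unique(records@label))
  take_tr <- take_va <- take_te <- integer(0)
  for (cl in classes) {
    idx <- which(records@label == cl)
    if (length(idx) < testPerClass)
      stop(sprintf("class '%s' has fewer records than testPerClass", cl))
    if (length(idx) < perClassTotal)
      warning(sprintf("class '%s': only %d of %d requested records available",
                      cl, length(idx), perClassTotal))
    # deterministic base order, then balanced subsampling per subtype
    idx <- idx[order(records@id[idx])]
    sub <- records@subtype[idx]
    sub[is.na(sub)] <- ""
    groups <- split(idx, sub)
    n_take <- min(perClassTotal, length(idx))
    picked <- .balanced_draw(groups, n_take)
    picked <- picked[sample.int(length(picked))]  # seeded shuffle
    te <- picked[seq_len(testPerClass)]
    pool <- picked[-seq_len(testPerClass)]
    n_tr <- floor(length(pool) * trainFraction)
    take_te <- c(take_te, te)
    take_tr <- c(take_tr, pool[seq_len(n_tr)])
    take_va <- c(take_va, pool[-seq_len(n_tr)])
  }
  split <- list(train = records[sort(take_tr)],
                validation = records[sort(take_va)],
                test = records[sort(take_te)])
  counts <- do.call(rbind, lapply(names(split), function(p)
    data.frame(partition = p,
               as.data.frame(table(classLabels(split[[p]]),
                                   dnn = "class")))))
  c(split, list(counts = counts))
}

# draw n_take elements spread equally over groups; remainders are taken in
# group-name order from the groups that still have spare records
.balanced_draw <- function(groups, n_take) {
  groups <- groups[order(names(groups))]
  sizes <- lengths(groups)
  alloc <- integer(length(groups))
  remaining <- n_take
  while (remaining > 0L) {
    open <- which(alloc < sizes)
    share <- remaining %/% length(open)
    if (share == 0L) {
      alloc[open[seq_len(remaining)]] <- alloc[open[seq_len(remaining)]] + 1L
      break
    }
    add <- pmin(sizes[open] - alloc[open], share)
    alloc[open] <- alloc[open] + add
    remaining <- remaining - sum(add)
    if (all(alloc == sizes)) break
  }
  unlist(lapply(seq_along(groups), function(g)
    groups[[g]][seq_len(alloc[g])]), use.names = FALSE)
}

#' Write a split manifest as TSV
#'
#' Columns: id, partition.
#'
#' @param split result of \code{\link{makeSplit}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSplitManifest <- function(split, path) {
  df <- do.call(rbind, lapply(c("train", "validation", "test"), function(p)
    data.frame(id = ids(split[[p]]), partition = p)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.FINE_RRNA <- c("5S" = "short rRNA", "5.8S" = "short rRNA",
                "23S" = "long rRNA", "25S" = "long rRNA",
                "28S" = "long rRNA", "SSU" = "long rRNA")

#' Expand 6-class labels to the 10-class fine-grained scheme
#'
#' snoRNAs split by subtype into C/D-Box, H/ACA-Box and scaRNA; rRNAs split
#' by subtype into short (5S, 5.8S) and long (23S, 25S, 28S, SSU); miRNAs
#' split by length into mature (15-30 nt) and precursor (39-6306 nt).
#' lncRNA, snRNA and tRNA pass through unchanged.  A snoRNA or rRNA without
#' a recognized subtype is an error.
#'
#' @param records an \linkS4class{NcRNASet} with 6-class labels.
#' @return the \linkS4class{NcRNASet} with 10-class labels.
#' @export
relabelFineGrained <- function(records) {
  lab <- records@label
  sub <- records@subtype
  len <- nchar(records@sequence)
  out <- lab
  for (i in seq_along(lab)) {
    out[i] <- switch(lab[i],
      snoRNA = {
        if (is.na(sub[i]) || !sub[i] %in% c("C/D-Box", "H/ACA-Box", "scaRNA"))
          stop(sprintf("snoRNA '%s' has unknown subtype '%s'",
                       records@id[i], sub[i]))
        sub[i]
      },
      rRNA = {
        if (is.na(sub[i]) || !sub[i] %in% names(.FINE_RRNA))
          stop(sprintf("rRNA '%s' has unknown subtype '%s'",
                       records@id[i], sub[i]))
        unname(.FINE_RRNA[sub[i]])
      },
      miRNA = {
        cls <- assignMirnaLengthClass(len[i])
        if (cls == "excluded")
          stop(sprintf("miRNA '%s' (%d nt) falls in the excluded 31-39 nt gap",
                       records@id[i], len[i]))
        paste(cls, "miRNA")
      },
      lab[i])
  }
  new("NcRNASet", id = records@id, sequence = records@sequence,
      label = out, subtype = records@subtype)
}

#' Coarsen fine-grained labels back to the 6-class scheme
#'
#' Inverse of \code{\link{relabelFineGrained}} on labels.
#'
#' @param labels character vector of 10-class labels.
#' @return character vector of 6-class labels.
#' @export
coarsenLabels <- function(labels) {
  map <- c("C/D-Box" = "snoRNA", "H/ACA-Box" = "snoRNA", "scaRNA" = "snoRNA",
           "short rRNA" = "rRNA", "long rRNA" = "rRNA",
           "mature miRNA" = "miRNA", "precursor miRNA" = "miRNA")
  out <- labels
  hit <- labels %in% names(map)
  out[hit] <- unname(map[labels[hit]])
  out
}
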