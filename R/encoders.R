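.SEQ_TOKENS <- c("_", "A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Sequence-channel vocabulary
#'
#' The 16 IUPAC nucleotide letters plus the padding character \code{"_"}: 17
#' tokens in total, coded 0..16 with \code{"_"} at 0 in the frozen order
#' \code{_ A C G T U R Y S W K M B D H V N}.
#'
#' @return named integer vector mapping token to code.
#' @examples
#' sequenceVocabulary()[["A"]]  # 1
#' @export
sequenceVocabulary <- function() {
  setNames(seq_along(.SEQ_TOKENS) - 1L, .SEQ_TOKENS)
}

.STRUCT_CHARS <- c(LETTERS[17:26], letters[1:14])  # Q..Z then a..n: 24 symbols

#' Combined nucleotide-substructure vocabulary
#'
#' 24 tokens for \{A, C, G, U\} x \{F, T, S, M, H, I\} (row-major over
#' nucleotides), plus \code{"N"} for an unknown nucleotide in any structure
#' and \code{"_"} for padding: 26 tokens coded 0..25 with \code{"_"} at 0 and
#' \code{"N"} at 25.  The combined characters run \code{Q..Z} then
#' \code{a..n}, anchored at (A, F) = \code{"Q"}.
#'
#' @return list with elements \code{code} (named integer vector token ->
#'   code), \code{pairChar} (4 x 6 character matrix indexed by nucleotide and
#'   state) and \code{tokens}.
#' @examples
#' structSeqVocabulary()$pairChar["A", "F"]  # "Q"
#' @export
structSeqVocabulary <- function() {
  nts <- c("A", "C", "G", "U")
  pairChar <- matrix(.STRUCT_CHARS, nrow = 4L, ncol = 6L, byrow = TRUE,
                     dimnames = list(nts, .STRUCT_STATES))
  tokens <- c("_", as.vector(t(pairChar)), "N")
  list(code = setNames(seq_along(tokens) - 1L, tokens),
       pairChar = pairChar, tokens = tokens)
}

.encode_chars <- function(chars, code, what) {
  idx <- match(chars, names(code))
  if (anyNA(idx)) {
    at <- which(is.na(idx))[1L]
    stop(sprintf("invalid %s character '%s' at position %d",
                 what, chars[at], at))
  }
  unname(code[idx])
}

#' Ordinal encoding of a primary sequence
#'
#' Maps each character to its integer code and right-pads with the padding
#' code 0 to \code{padTo} positions (default 12000).  \code{T} and \code{U}
#' are distinct tokens; input case is normalized.
#'
#' @param sequence IUPAC string, at most \code{padTo} characters.
#' @param vocab vocabulary from \code{\link{sequenceVocabulary}}.
#' @param padTo output length.
#' @return an \linkS4class{EncodedInput} with \code{channel = "sequence"}.
#' @examples
#' head(encodedValues(encodeSequence("ACGU", padTo = 10)), 6)
#' @export
encodeSequence <- function(sequence, vocab = sequenceVocabulary(),
                           padTo = 12000L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n > padTo) stop("sequence exceeds maximum length")
  chars <- if (n) strsplit(sequence, "", fixed = TRUE)[[1L]] else character(0)
  codes <- .encode_chars(chars, vocab, "sequence")
  new("EncodedInput",
      values = as.integer(c(codes, integer(padTo - n))),
      channel = "sequence")
}

#' Combined nucleotide-structure encoding
#'
#' Each position maps its (nucleotide, substructure state) pair to the
#' combined token; \code{T} is normalized to \code{U} first, and any other
#' non-ACGU nucleotide maps to the \code{"N"} token regardless of the
#' predicted structure.  Right-padded with 0.
#'
#' @param sequence IUPAC string.
#' @param annotation substructure states over \{F, T, S, M, H, I\}, same
#'   length as \code{sequence} (see \code{\link{annotateStructure}}).
#' @param vocab vocabulary from \code{\link{structSeqVocabulary}}.
#' @param padTo output length.
#' @return an \linkS4class{EncodedInput} with \code{channel = "structure"}.
#' @export
encodeStructSequence <- function(sequence, annotation,
                                 vocab = structSeqVocabulary(),
                                 padTo = 12000L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(annotation))
    stop("sequence and annotation lengths differ")
  n <- nchar(sequence)
  if (n > padTo) stop("sequence exceeds maximum length")
  if (n == 0L)
    return(new("EncodedInput", values = integer(padTo), channel = "structure"))
  nts <- strsplit(chartr("T", "U", sequence), "", fixed = TRUE)[[1L]]
  sts <- strsplit(annotation, "", fixed = TRUE)[[1L]]
  if (!all(sts %in% .STRUCT_STATES))
    stop("invalid substructure state in annotation")
  known <- nts %in% rownames(vocab$pairChar)
  tok <- character(n)
  tok[known] <- vocab$pairChar[cbind(nts[known], sts[known])]
  tok[!known] <- "N"
  codes <- .encode_chars(tok, vocab$code, "combined-alphabet")
  new("EncodedInput",
      values = as.integer(c(codes, integer(padTo - n))),
      channel = "structure")
}

#' Values of an encoded input
#' @param x an \linkS4class{EncodedInput}.
#' @return integer vector.
#' @export
encodedValues <- function(x) x@values

#' Decode an encoded input back to a string
#'
#' Inverse of \code{\link{encodeSequence}} (or, for the structure channel,
#' recovers the combined-token string): trailing padding is removed.
#'
#' @param x an \linkS4class{EncodedInput}.
#' @return character string.
#' @export
decodeInput <- function(x) {
  tokens <- if (x@channel == "sequence") .SEQ_TOKENS
            else structSeqVocabulary()$tokens
  v <- x@values
  n <- length(v)
  while (n > 0L && v[n] == 0L) n <- n - 1L
  if (n == 0L) return("")
  paste(tokens[v[seq_len(n)] + 1L], collapse = "")
}

#' Graph-encoder configuration constructor
#'
#' @param maxRadius neighborhood radius.
#' @param maxDistance maximum root-pair distance.
#' @param hashBits feature-hash width (vector dimension is \code{2^hashBits}).
#' @return a \linkS4class{GraphEncoderConfig}.
#' @export
graphEncoderConfig <- function(maxRadius = 1L, maxDistance = 4L,
                               hashBits = 15L) {
  new("GraphEncoderConfig", maxRadius = as.integer(maxRadius),
      maxDistance = as.integer(maxDistance), hashBits = as.integer(hashBits))
}

#' Build the sequence-structure graph of one window structure
#' @keywords internal
.shrep_graph <- function(window_seq, db) {
  n <- nchar(window_seq)
  states <- strsplit(annotateStructure(window_seq, db), "", fixed = TRUE)[[1L]]
  nts <- strsplit(chartr("T", "U", toupper(window_seq)), "", fixed = TRUE)[[1L]]
  labels <- paste0(nts, states)
  p <- pairTable(db)
  pair_i <- which(p > seq_along(p))
  from <- c(seq_len(max(n - 1L, 0L)), pair_i)
  to <- c(seq_len(max(n - 1L, 0L)) + 1L, p[pair_i])
  list(labels = labels, from = from, to = to)
}

#' Hashed weighted graph-feature vector
#'
#' Per structure representative, the window is turned into a graph whose
#' vertices are positions labeled with nucleotide plus substructure state,
#' with backbone edges between consecutive positions and pair edges between
#' paired positions.  Neighborhood-subgraph pair features (radius up to
#' \code{maxRadius}, root distance up to \code{maxDistance}) are hashed with
#' a fixed platform-independent string hash to \code{2^hashBits} buckets and
#' their counts accumulated across all representatives of all windows.
#'
#' @param sequence the RNA sequence the shreps were produced from.
#' @param shreps a \linkS4class{ShrepSet} for \code{sequence}.
#' @param config a \linkS4class{GraphEncoderConfig}.
#' @return a \code{\link[Matrix]{sparseVector}} of length \code{2^hashBits}
#'   with nonnegative weights.
#' @export
encodeGraph <- function(sequence, shreps = NULL,
                        config = graphEncoderConfig()) {
  dim <- 2L^config@hashBits
  if (nchar(sequence) == 0L)
    return(Matrix::sparseVector(numeric(0), integer(0), length = dim))
  if (is.null(shreps)) shreps <- windowedShreps(sequence)
  if (!identical(toupper(shreps@sequence), toupper(sequence)))
    stop("shreps were produced from a different sequence")
  len <- nchar(sequence)
  all_idx <- list(); all_w <- list(); n_parts <- 0L
  for (k in seq_along(shreps@offsets)) {
    o <- shreps@offsets[k]
    w <- substr(sequence, o + 1L, min(len, o + shreps@windowSize))
    for (db in shreps@structures[[k]]) {
      g <- .shrep_graph(w, db)
      f <- .nspdk_features_cpp(g$labels, as.integer(g$from), as.integer(g$to),
                               config@maxRadius, config@maxDistance,
                               config@hashBits)
      n_parts <- n_parts + 1L
      all_idx[[n_parts]] <- f$index
      all_w[[n_parts]] <- f$weight
    }
  }
  idx <- unlist(all_idx) + 1L
  agg <- rowsum(unlist(all_w), idx)
  ui <- as.integer(rownames(agg))
  ord <- order(ui)
  Matrix::sparseVector(x = as.numeric(agg[ord, 1L]), i = ui[ord],
                       length = dim)
}

#' Encode a set of sequences as model-ready matrices
#'
#' Convenience wrappers producing one row per record.
#'
#' @param x an \linkS4class{NcRNASet} or character vector of sequences.
#' @param padTo padded length for the dense channels.
#' @param channel \code{"sequence"}, \code{"structure"} or \code{"graph"}.
#' @param foldingCfg \linkS4class{FoldingConfig} used for the structure and
#'   graph channels.
#' @param graphCfg \linkS4class{GraphEncoderConfig} for the graph channel.
#' @return integer matrix (dense channels) or \code{dgCMatrix} (graph
#'   channel) with rownames set to record ids.
#' @export
encodeSet <- function(x, channel = c("sequence", "structure", "graph"),
                      padTo = 12000L, foldingCfg = foldingConfig(),
                      graphCfg = graphEncoderConfig()) {
  channel <- match.arg(channel)
  seqs <- if (is(x, "NcRNASet")) sequences(x) else
    setNames(toupper(x), names(x) %||% paste0("seq", seq_along(x)))
  if (channel == "sequence") {
    vocab <- sequenceVocabulary()
    m <- t(vapply(seqs, function(s)
      encodedValues(encodeSequence(s, vocab, padTo)), integer(padTo)))
    rownames(m) <- names(seqs)
    return(m)
  }
  if (channel == "structure") {
    vocab <- structSeqVocabulary()
    m <- t(vapply(seqs, function(s) {
      db <- foldMFE(substr(s, 1L, padTo), foldingCfg)
      ann <- annotateStructure(substr(s, 1L, padTo), db)
      encodedValues(encodeStructSequence(substr(s, 1L, padTo), ann,
                                         vocab, padTo))
    }, integer(padTo)))
    rownames(m) <- names(seqs)
    return(m)
  }
  dim <- 2L^graphCfg@hashBits
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (r in seq_along(seqs)) {
    v <- encodeGraph(seqs[r], windowedShreps(seqs[r], foldingCfg), graphCfg)
    trip_i[[r]] <- rep.int(r, length(v@i))
    trip_j[[r]] <- v@i
    trip_x[[r]] <- v@x
  }
  m <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(length(seqs), dim))
  rownames(m) <- names(seqs)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise L2 normalization
#'
#' Scales every row of a (sparse) feature matrix to unit Euclidean norm;
#' zero rows are left untouched.  The usual preprocessing for hashed
#' graph-kernel count vectors before they enter a dense network.
#'
#' @param m numeric matrix or \code{dgCMatrix}.
#' @return the normalized matrix, same class as the input.
#' @export
normalizeRows <- function(m) {
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  if (is(m, "sparseMatrix")) Matrix::Diagonal(x = 1 / nrm) %*% m
  else m / nrm
}

#' Write a graph-feature matrix in MatrixMarket format
#'
#' @param m \code{dgCMatrix} of graph vectors (rows = records).
#' @param path output \code{.mtx} file; a sidecar \code{<path>.rows.tsv}
#'   holds the id-to-row index.
#' @return invisibly, the path.
#' @export
writeGraphMatrix <- function(m, path) {
  Matrix::writeMM(m, path)
  write.table(data.frame(row = seq_len(nrow(m)), id = rownames(m)),
              paste0(path, ".rows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
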