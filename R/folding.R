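#' Folding configuration constructor
#'
#' Defaults mirror the windowed structure-prediction parameters used for the
#' graph channel: 150-nt windows, a shift of 25\% of the window and 3
#' structure representatives ("shreps") per window.
#'
#' @param windowSize window length in nt.
#' @param shiftFraction shift as a fraction of the window, in (0, 1].
#' @param nShreps representatives per window.
#' @param minHairpin minimum unpaired positions in a hairpin loop.
#' @param engine \code{"builtin_nussinov"} (the built-in base-pair
#'   maximization engine) or \code{"external_mfe"} (delegate to an installed
#'   \code{RNAfold} binary when present).
#' @return a \linkS4class{FoldingConfig}.
#' @export
foldingConfig <- function(windowSize = 150L, shiftFraction = 0.25,
                          nShreps = 3L, minHairpin = 3L,
                          engine = "builtin_nussinov") {
  new("FoldingConfig", windowSize = as.integer(windowSize),
      shiftFraction = as.numeric(shiftFraction),
      nShreps = as.integer(nShreps), minHairpin = as.integer(minHairpin),
      engine = engine)
}

.check_rna <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTURYSWKMBDHVN]", sequence)
  if (bad > 0L)
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  sequence
}

#' Predict a secondary structure in dot-bracket notation
#'
#' The built-in engine maximizes the number of nested Watson-Crick and GU
#' wobble pairs (Nussinov-style dynamic programming) subject to a minimum
#' hairpin size; IUPAC ambiguity codes are unpairable and \code{T} pairs like
#' \code{U}.  The result is deterministic for a fixed input.
#'
#' @param sequence RNA string (IUPAC alphabet; case-insensitive).
#' @param config a \linkS4class{FoldingConfig}.
#' @param forbid optional 2-column matrix of 1-based pairs that must not form
#'   (used to generate suboptimal representatives).
#' @return dot-bracket string of the same length as \code{sequence}.
#' @examples
#' foldMFE("GGGGAAAACCCC")
#' @export
foldMFE <- function(sequence, config = foldingConfig(), forbid = NULL) {
  if (nchar(sequence) == 0L) return("")
  sequence <- .check_rna(sequence)
  if (config@engine == "external_mfe") {
    ext <- .fold_external(sequence)
    if (!is.null(ext)) return(ext)
    # fall through to the builtin engine when no external folder is found
  }
  if (is.null(forbid)) forbid <- matrix(integer(0), ncol = 2L)
  .nussinov_fold_cpp(sequence, config@minHairpin,
                     as.integer(forbid[, 1L]), as.integer(forbid[, 2L]))
}

.fold_external <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) return(NULL)
  out <- tryCatch(
    system2(exe, c("--noPS"), input = sequence, stdout = TRUE, stderr = FALSE),
    error = function(e) NULL)
  if (is.null(out) || length(out) < 2L) return(NULL)
  sub("^([().]+).*$", "\\1", out[2L])
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db dot-bracket string.
#' @return integer vector p with p[i] = partner of i (0 when unpaired).
#' @export
pairTable <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") {
      stop(sprintf("invalid dot-bracket character '%s'", ch[i]))
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  p
}

#' Window shift in nucleotides
#'
#' \code{floor(windowSize * shiftFraction)}, clamped to a minimum of 1; with
#' the default 150-nt window and 25\% shift this is 37 nt.
#'
#' @param windowSize window length in nt.
#' @param shiftFraction shift fraction in (0, 1].
#' @return integer shift in nt.
#' @examples
#' computeShift(150, 0.25)  # 37
#' @export
computeShift <- function(windowSize, shiftFraction) {
  stopifnot(windowSize >= 1L)
  max(1L, as.integer(floor(windowSize * shiftFraction)))
}

#' Window offsets covering a sequence
#' @keywords internal
.window_offsets <- function(len, windowSize, shiftFraction) {
  if (len <= windowSize) return(0L)
  s <- computeShift(windowSize, shiftFraction)
  offs <- seq.int(0L, by = s, length.out = (len - windowSize) %/% s + 1L)
  last <- as.integer(len - windowSize)
  if (offs[length(offs)] < last) offs <- c(offs, last)
  offs
}

#' Windowed structure representatives
#'
#' Slides a window over the sequence (offsets 0, s, 2s, ... for shift s, with
#' the final window anchored at \code{length - windowSize} so that every
#' window is full-width) and folds each window \code{nShreps} times.  The
#' built-in engine returns the optimal structure plus up to
#' \code{nShreps - 1} distinct suboptimal structures, generated by
#' iteratively forbidding the 5'-most pair of the latest structure and
#' refolding; duplicates are dropped.
#'
#' @param sequence non-empty RNA string.
#' @param config a \linkS4class{FoldingConfig}.
#' @return a \linkS4class{ShrepSet}.
#' @examples
#' windowedShreps(paste(rep("GACU", 50), collapse = ""))
#' @export
windowedShreps <- function(sequence, config = foldingConfig()) {
  if (nchar(sequence) == 0L) stop("empty input")
  sequence <- .check_rna(sequence)
  len <- nchar(sequence)
  offs <- .window_offsets(len, config@windowSize, config@shiftFraction)
  structures <- lapply(offs, function(o) {
    w <- substr(sequence, o + 1L, min(len, o + config@windowSize))
    reps <- character(0)
    forbid <- matrix(integer(0), ncol = 2L)
    db <- foldMFE(w, config)
    repeat {
      if (!db %in% reps) reps <- c(reps, db)
      if (length(reps) >= config@nShreps) break
      p <- pairTable(db)
      opening <- which(p > seq_along(p))
      if (!length(opening)) break
      i <- opening[1L]
      forbid <- rbind(forbid, c(i, p[i]))
      db2 <- foldMFE(w, config, forbid = forbid)
      if (identical(db2, db) && db %in% reps) break
      db <- db2
    }
    reps
  })
  new("ShrepSet", sequence = sequence, offsets = as.integer(offs),
      structures = structures, windowSize = config@windowSize)
}

setMethod("show", "ShrepSet", function(object) {
  cat(sprintf("ShrepSet: %d nt, %d window(s) of %d nt, %d structure(s)\n",
              nchar(object@sequence), length(object@offsets),
              object@windowSize, sum(lengths(object@structures))))
  invisible(object)
})

#' Annotate each position with a substructure state
#'
#' Derives the six-state annotation from a dot-bracket structure: paired
#' positions are stems (\code{S}); unpaired positions take the state of
#' their enclosing loop — hairpin loop (\code{H}) when the loop closes no
#' further helix, internal loop or bulge (\code{I}) when it closes exactly
#' one, multi-loop (\code{M}) when it closes two or more.  External unpaired
#' positions are \code{F} before the first paired position, \code{T} after
#' the last, and \code{M} between two top-level helices.  A fully unpaired
#' structure annotates as all \code{F}.
#'
#' @param sequence the sequence (same length as \code{db}).
#' @param db dot-bracket string.
#' @return string over \{F, T, S, M, H, I\} of the same length.
#' @examples
#' annotateStructure("GGGGAAAACCCC", "((((....))))")  # "SSSSHHHHSSSS"
#' @export
annotateStructure <- function(sequence, db) {
  if (nchar(sequence) != nchar(db))
    stop("sequence and structure lengths differ")
  n <- nchar(db)
  if (n == 0L) return("")
  p <- pairTable(db)
  states <- character(n)
  if (!any(p > 0L)) return(strrep("F", n))

  states[p > 0L] <- "S"
  first_pair <- min(which(p > 0L))
  last_pair <- max(which(p > 0L))

  # enclosing pair of every position (0 = external) via a stack sweep
  enclosing <- integer(n)
  cur <- 0L
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      enclosing[i] <- cur
      cur <- i
    } else if (ch[i] == ")") {
      cur <- enclosing[p[i]]
      enclosing[i] <- cur
    } else {
      enclosing[i] <- cur
    }
  }

  # number of helices branching directly from the loop closed by pair (i, j)
  n_children <- function(i) {
    j <- p[i]
    k <- i + 1L
    nb <- 0L
    while (k < j) {
      if (p[k] > k) {
        nb <- nb + 1L
        k <- p[k] + 1L
      } else k <- k + 1L
    }
    nb
  }
  child_cache <- new.env(parent = emptyenv())
  loop_state <- function(i) {
    key <- as.character(i)
    if (!is.null(child_cache[[key]])) return(child_cache[[key]])
    nb <- n_children(i)
    st <- if (nb == 0L) "H" else if (nb == 1L) "I" else "M"
    child_cache[[key]] <- st
    st
  }

  unpaired <- which(p == 0L)
  for (i in unpaired) {
    if (enclosing[i] == 0L) {
      states[i] <- if (i < first_pair) "F" else if (i > last_pair) "T" else "M"
    } else {
      states[i] <- loop_state(enclosing[i])
    }
  }
  paste(states, collapse = "")
}

#' Write sequences and structures in Vienna style
#'
#' One record per sequence: a header line, the sequence line and the
#' dot-bracket line.
#'
#' @param ids character ids.
#' @param seqs character sequences.
#' @param dbs character dot-bracket strings.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDotBracket <- function(ids, seqs, dbs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ids))
    writeLines(c(paste0(">", ids[k]), seqs[k], dbs[k]), con)
  invisible(path)
}

#' Serialize a ShrepSet as TSV
#'
#' Columns: id, offset (0-based), structure.
#'
#' @param id sequence id.
#' @param shreps a \linkS4class{ShrepSet}.
#' @param path output file; when \code{NULL} the data.frame is returned.
#' @return the data.frame, invisibly when written.
#' @export
writeShrepsTSV <- function(id, shreps, path = NULL) {
  df <- do.call(rbind, lapply(seq_along(shreps@offsets), function(k)
    data.frame(id = id, offset = shreps@offsets[k],
               structure = shreps@structures[[k]],
               stringsAsFactors = FALSE)))
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
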