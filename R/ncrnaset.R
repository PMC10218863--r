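#' Construct a labeled ncRNA sequence set
#'
#' @param id character accessions (unique).
#' @param sequence character sequences (normalized to uppercase).
#' @param label character class labels.
#' @param subtype optional character subtypes.
#' @return an \linkS4class{NcRNASet}.
#' @examples
#' NcRNASet(c("a", "b"), c("ACGU", "GGGCCC"), c("tRNA", "rRNA"))
#' @export
NcRNASet <- function(id, sequence, label, subtype = NA_character_) {
  n <- length(id)
  new("NcRNASet",
      id = as.character(id),
      sequence = toupper(as.character(sequence)),
      label = as.character(rep_len(label, n)),
      subtype = as.character(rep_len(subtype, n)))
}

#' Accessors for NcRNASet
#'
#' @param x an \linkS4class{NcRNASet}.
#' @return the corresponding per-record vector.
#' @name ncRNASet-accessors
NULL

#' @rdname ncRNASet-accessors
#' @export
setMethod("ids", "NcRNASet", function(x) x@id)
#' @rdname ncRNASet-accessors
#' @export
setMethod("sequences", "NcRNASet", function(x) setNames(x@sequence, x@id))
#' @rdname ncRNASet-accessors
#' @export
setMethod("classLabels", "NcRNASet", function(x) x@label)
#' @rdname ncRNASet-accessors
#' @export
setMethod("subtypes", "NcRNASet", function(x) x@subtype)
#' @rdname ncRNASet-accessors
#' @export
setMethod("seqLengths", "NcRNASet", function(x) nchar(x@sequence))

#' @export
setMethod("length", "NcRNASet", function(x) length(x@id))

#' @export
setMethod("[", "NcRNASet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@id)
  new("NcRNASet", id = x@id[i], sequence = x@sequence[i],
      label = x@label[i], subtype = x@subtype[i])
})

#' Combine ncRNA sets
#' @param x,... \linkS4class{NcRNASet} objects.
#' @return the concatenated \linkS4class{NcRNASet}.
#' @export
setMethod("c", "NcRNASet", function(x, ...) {
  rest <- list(...)
  new("NcRNASet",
      id = c(x@id, unlist(lapply(rest, function(y) y@id))),
      sequence = c(x@sequence, unlist(lapply(rest, function(y) y@sequence))),
      label = c(x@label, unlist(lapply(rest, function(y) y@label))),
      subtype = c(x@subtype, unlist(lapply(rest, function(y) y@subtype))))
})

setMethod("show", "NcRNASet", function(object) {
  cat(sprintf("NcRNASet with %d records\n", length(object)))
  if (length(object)) {
    tab <- table(object@label)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
    cat(sprintf("  lengths: %d..%d nt\n",
                min(nchar(object@sequence)), max(nchar(object@sequence))))
  }
  invisible(object)
})

#' Convert an NcRNASet to a data.frame
#'
#' @param x an \linkS4class{NcRNASet}.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame with columns id, sequence, label, subtype, length.
#' @export
as.data.frame.NcRNASet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(id = x@id, sequence = x@sequence, label = x@label,
             subtype = x@subtype, length = nchar(x@sequence),
             stringsAsFactors = FALSE)
}
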