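#' Build a confusion matrix
#'
#' Rows are true labels, columns predicted labels, in the frozen class
#' order.
#'
#' @param true,predicted equal-length label vectors; every label must be in
#'   \code{classes}.
#' @param classes class order.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusion <- function(true, predicted, classes = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  if (!all(true %in% classes))
    stop(sprintf("unknown true label '%s'", setdiff(true, classes)[1L]))
  if (!all(predicted %in% classes))
    stop(sprintf("unknown predicted label '%s'",
                 setdiff(predicted, classes)[1L]))
  counts <- table(factor(true, classes), factor(predicted, classes))
  m <- matrix(as.integer(counts), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  new("ConfusionMatrix", counts = m, classes = as.character(classes))
}

#' Row-normalized view of a confusion matrix
#'
#' Each row is divided by its total (rows without samples stay 0); for
#' rendering, cells below \code{threshold} can be blanked — this affects
#' display only, never computation.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @param threshold cells strictly below it become \code{NA} (default 0,
#'   i.e. keep everything; the figure convention is 0.005).
#' @return numeric matrix of row fractions.
#' @export
rowNormalize <- function(cm, threshold = 0) {
  rs <- rowSums(cm@counts)
  m <- cm@counts / ifelse(rs == 0, 1, rs)
  if (threshold > 0) m[m < threshold] <- NA_real_
  m
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix over %d classes, %d samples\n",
              length(object@classes), sum(object@counts)))
  print(object@counts)
  invisible(object)
})

#' Score a confusion matrix
#'
#' Per-class precision (diagonal over column sum), recall (diagonal over
#' row sum) and F1 (harmonic mean, 0 when both are 0); macro scores as
#' unweighted class means, excluding classes with neither true nor
#' predicted samples; and the multiclass Matthews correlation coefficient
#' computed from the full matrix,
#' \deqn{MCC = (c s - \sum_k p_k t_k) /
#'   \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}
#' with \eqn{c} the trace, \eqn{s} the total and \eqn{p_k, t_k} the
#' predicted/true class totals (0 when a factor is degenerate).
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @param correctIds optional ids of the correctly classified records (the
#'   matrix itself does not retain ids).
#' @return an \linkS4class{EvaluationReport}.
#' @export
scores <- function(cm, correctIds = character(0)) {
  m <- cm@counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  diag_ <- diag(m)
  colS <- colSums(m)
  rowS <- rowSums(m)
  precision <- ifelse(colS == 0, 0, diag_ / colS)
  recall <- ifelse(rowS == 0, 0, diag_ / rowS)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  present <- rowS > 0 | colS > 0
  s <- total
  c_ <- sum(diag_)
  num <- c_ * s - sum(colS * rowS)
  den <- sqrt(s^2 - sum(colS^2)) * sqrt(s^2 - sum(rowS^2))
  mcc <- if (den == 0) 0 else num / den
  new("EvaluationReport",
      perClass = data.frame(class = cm@classes, precision = unname(precision),
                            recall = unname(recall), f1 = unname(f1)),
      macroPrecision = mean(precision[present]),
      macroRecall = mean(recall[present]),
      macroF1 = mean(f1[present]),
      mcc = mcc, confusion = cm, correctIds = correctIds)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport: macro P %.4f / R %.4f / F1 %.4f, ",
                     "MCC %.4f (%d samples)\n"),
              object@macroPrecision, object@macroRecall, object@macroF1,
              object@mcc, sum(object@confusion@counts)))
  print(object@perClass, row.names = FALSE, digits = 4)
  invisible(object)
})

#' Evaluate predictions directly
#'
#' @param true,predicted label vectors.
#' @param classes class order.
#' @param ids optional record ids (used to fill the correct-id set).
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluatePredictions <- function(true, predicted,
                                classes = sort(unique(c(true, predicted))),
                                ids = NULL) {
  cm <- confusion(true, predicted, classes)
  correct <- if (is.null(ids)) character(0) else ids[true == predicted]
  scores(cm, correctIds = correct)
}

#' Write an evaluation report
#'
#' Per-class table as TSV and the full report as JSON.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param tsv,json output paths (either may be NULL).
#' @return invisibly, the report.
#' @export
writeReport <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(report@perClass, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(perClass = report@perClass,
           macro = list(precision = report@macroPrecision,
                        recall = report@macroRecall, f1 = report@macroF1),
           mcc = report@mcc,
           confusion = as.data.frame(report@confusion@counts)),
      json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Correctness-overlap region counts
#'
#' For m models with their sets of correctly classified ids over one shared
#' universe, counts every membership region (all \code{2^m - 1} non-empty
#' combinations, exclusive) plus the ids no model got right; the regions
#' partition the universe.
#'
#' @param sets named list of character id sets.
#' @param universe all scored ids.
#' @return named integer vector; combination names join set names with
#'   \code{"&"}, plus \code{"none"}.
#' @export
overlapSets <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% universe))
      stop(sprintf("set '%s' contains ids outside the universe", nm))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  m <- length(sets)
  out <- integer(0)
  for (mask in seq_len(2^m - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    hit <- rowSums(member[, inset, drop = FALSE] + 0) == sum(inset) &
           rowSums(member[, !inset, drop = FALSE] + 0) == 0
    out[paste(names(sets)[inset], collapse = "&")] <- sum(hit)
  }
  out["none"] <- sum(rowSums(member + 0) == 0)
  out
}

#' Default harmonization rules for the 4-class benchmark
#'
#' Fine-grained labels collapse to their parent class (C/D-Box, H/ACA-Box
#' and scaRNA to snoRNA; 5S and 5.8S rRNA to rRNA); labels present in only
#' one scheme (Ribozyme, the group I/II introns, Riboswitch, IRES, Leader,
#' lncRNA, snRNA) are dropped; sequences longer than 750 nt and mature-
#' length miRNAs are excluded, as are sequences more than 90\% identical to
#' the reference training set.
#'
#' @return a \linkS4class{HarmonizationRules}.
#' @export
defaultHarmonizationRules <- function() {
  keep4 <- c("miRNA", "rRNA", "snoRNA", "tRNA")
  map <- c(setNames(keep4, keep4),
           "CD-Box" = "snoRNA", "C/D-Box" = "snoRNA",
           "HACA-Box" = "snoRNA", "H/ACA-Box" = "snoRNA",
           "scaRNA" = "snoRNA",
           "5S rRNA" = "rRNA", "5.8S rRNA" = "rRNA",
           "Ribozyme" = "DROP", "Intron gpI" = "DROP",
           "Intron gpII" = "DROP", "Riboswitch" = "DROP",
           "IRES" = "DROP", "Leader" = "DROP",
           "lncRNA" = "DROP", "snRNA" = "DROP",
           "(invalid)" = "DROP")
  new("HarmonizationRules", labelMap = map, maxLength = 750L,
      excludeMatureMirna = TRUE, similarityThreshold = 0.90)
}

#' Read harmonization rules from a YAML map
#'
#' The file holds \code{label_map} (source label to target label or
#' \code{DROP}) and optionally \code{max_length},
#' \code{exclude_mature_mirna} and \code{similarity_threshold}; omitted
#' fields keep the defaults of \code{\link{defaultHarmonizationRules}}.
#'
#' @param path YAML file.
#' @return a \linkS4class{HarmonizationRules}.
#' @export
readHarmonizationRules <- function(path) {
  y <- yaml::read_yaml(path)
  base <- defaultHarmonizationRules()
  map <- if (is.null(y$label_map)) base@labelMap
         else unlist(y$label_map)
  new("HarmonizationRules",
      labelMap = map,
      maxLength = as.integer(y$max_length %||% base@maxLength),
      excludeMatureMirna = as.logical(y$exclude_mature_mirna %||%
                                        base@excludeMatureMirna),
      similarityThreshold = as.numeric(y$similarity_threshold %||%
                                         base@similarityThreshold))
}

#' Harmonize heterogeneous benchmark predictions
#'
#' Applies the label-merging and eligibility rules used when two
#' classifiers with different label schemes are compared: records whose
#' true label maps to \code{DROP}, records longer than \code{maxLength},
#' mature-length miRNAs (when configured) and records above the similarity
#' threshold to the reference training set are excluded; surviving true and
#' predicted labels are mapped to the shared scheme and scored on mapped
#' -label equality.  A prediction mapping to \code{DROP} (a label absent
#' from the shared scheme) counts as incorrect.
#'
#' @param records an \linkS4class{NcRNASet} of benchmark records.
#' @param predictions named character vector: predicted label per record id.
#' @param rules a \linkS4class{HarmonizationRules}.
#' @param reference optional \linkS4class{NcRNASet} of training sequences
#'   for the similarity screen (skipped when NULL).
#' @return data.frame with columns id, true, predicted (mapped labels;
#'   dropped predictions become \code{"(invalid)"}) and correct.
#' @export
harmonize <- function(records, predictions, rules = defaultHarmonizationRules(),
                      reference = NULL) {
  lab <- records@label
  unmapped <- setdiff(c(lab, unname(predictions)), names(rules@labelMap))
  if (length(unmapped))
    stop(sprintf("unmapped label '%s'", unmapped[1L]))
  keep <- rules@labelMap[lab] != "DROP" &
          nchar(records@sequence) <= rules@maxLength
  if (rules@excludeMatureMirna)
    keep <- keep & !(lab == "miRNA" &
                     assignMirnaLengthClass(nchar(records@sequence)) == "mature")
  if (!is.null(reference) && length(reference)) {
    sim <- maxIdentityTo(records, reference)
    keep <- keep & sim <= rules@similarityThreshold
  }
  kept <- records[which(keep)]
  pred <- predictions[ids(kept)]
  if (anyNA(pred)) stop("missing prediction for a surviving record")
  true_m <- unname(rules@labelMap[classLabels(kept)])
  pred_m <- unname(rules@labelMap[pred])
  pred_m[pred_m == "DROP"] <- "(invalid)"
  data.frame(id = ids(kept), true = true_m, predicted = pred_m,
             correct = true_m == pred_m, stringsAsFactors = FALSE)
}
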