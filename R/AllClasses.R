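#' @useDynLib mncr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom Matrix sparseVector sparseMatrix Diagonal writeMM
#' @importFrom stats median runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

.NCRNA_CLASSES <- c("lncRNA", "miRNA", "rRNA", "snRNA", "snoRNA", "tRNA")
.FINE_CLASSES <- c("lncRNA", "mature miRNA", "precursor miRNA",
                   "short rRNA", "long rRNA", "snRNA",
                   "C/D-Box", "H/ACA-Box", "scaRNA", "tRNA")
.STRUCT_STATES <- c("F", "T", "S", "M", "H", "I")

#' Labeled set of non-coding RNA sequences
#'
#' The central container of the package: a set of RNA (or DNA-alphabet)
#' sequences with a class label and an optional subtype per record.
#' Sequences are stored uppercase over the IUPAC alphabet; both \code{T} and
#' \code{U} are allowed so that database exports in either convention can be
#' consumed unchanged.
#'
#' @slot id character vector of unique accessions.
#' @slot sequence character vector of uppercase IUPAC sequences.
#' @slot label character vector of class labels.
#' @slot subtype character vector of subtypes (\code{NA} when absent).
#' @export
setClass("NcRNASet", representation(
  id = "character", sequence = "character",
  label = "character", subtype = "character"
))

setValidity("NcRNASet", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@label) != n ||
      length(object@subtype) != n)
    return("id, sequence, label and subtype must have equal length")
  if (anyDuplicated(object@id))
    return("duplicate ids are not allowed")
  bad <- grepl("[^ACGTURYSWKMBDHVN]", object@sequence)
  if (any(bad))
    return(sprintf("sequence %s contains non-IUPAC characters",
                   object@id[which(bad)[1L]]))
  TRUE
})

#' Folding configuration
#'
#' Parameters of the windowed secondary-structure prediction: windows of
#' \code{windowSize} nucleotides shifted by \code{shiftFraction} of the
#' window, with up to \code{nShreps} structure representatives per window.
#'
#' @slot windowSize window length in nt (default 150).
#' @slot shiftFraction window shift as a fraction of the window (default 0.25).
#' @slot nShreps number of structure representatives per window (default 3).
#' @slot minHairpin minimum unpaired positions in a hairpin loop (default 3).
#' @slot engine folding engine, currently \code{"builtin_nussinov"}.
#' @export
setClass("FoldingConfig", representation(
  windowSize = "integer", shiftFraction = "numeric",
  nShreps = "integer", minHairpin = "integer", engine = "character"
))

setValidity("FoldingConfig", function(object) {
  if (object@windowSize < 1L) return("windowSize must be >= 1")
  if (object@shiftFraction <= 0 || object@shiftFraction > 1)
    return("shiftFraction must be in (0, 1]")
  if (object@nShreps < 1L) return("nShreps must be >= 1")
  if (!object@engine %in% c("builtin_nussinov", "external_mfe"))
    return("unknown engine")
  TRUE
})

#' Windowed structure representatives for one sequence
#'
#' @slot sequence the folded sequence.
#' @slot offsets 0-based window offsets, strictly increasing.
#' @slot structures list (one element per window) of character vectors of
#'   dot-bracket strings, each the length of the window.
#' @slot windowSize window length used.
#' @export
setClass("ShrepSet", representation(
  sequence = "character", offsets = "integer",
  structures = "list", windowSize = "integer"
))

setValidity("ShrepSet", function(object) {
  if (length(object@offsets) != length(object@structures))
    return("offsets and structures must align")
  if (is.unsorted(object@offsets, strictly = TRUE))
    return("offsets must be strictly increasing")
  TRUE
})

#' Graph-encoder configuration
#'
#' @slot maxRadius neighborhood radius (default 1).
#' @slot maxDistance maximum root-pair distance (default 4).
#' @slot hashBits feature-hash width; the vector has \code{2^hashBits}
#'   dimensions (default 15, i.e. 32768).
#' @export
setClass("GraphEncoderConfig", representation(
  maxRadius = "integer", maxDistance = "integer", hashBits = "integer"
))

#' Encoded model input
#'
#' A padded integer vector for the sequence or structure channel.
#'
#' @slot values integer vector of token codes, length \code{padTo}.
#' @slot channel \code{"sequence"} or \code{"structure"}.
#' @export
setClass("EncodedInput", representation(
  values = "integer", channel = "character"
))

#' Declarative neural-architecture specification
#'
#' @slot name one of \code{"GrEnc"}, \code{"SeqEnc"}, \code{"StrEnc"},
#'   \code{"MncR"}.
#' @slot branches list of branches; each branch is a list of layer
#'   specifications ending in a dense layer.
#' @slot head list of layer specifications applied after concatenating the
#'   branch outputs (solo models have a single branch and the softmax output
#'   lives in the branch itself).
#' @slot nClasses number of output classes.
#' @export
setClass("ModelSpec", representation(
  name = "character", branches = "list", head = "list", nClasses = "integer"
))

#' Realized neural model
#'
#' A \linkS4class{ModelSpec} together with initialized (or trained) weights.
#'
#' @slot spec the architecture specification.
#' @slot weights nested list of numeric arrays, one entry per parameterized
#'   layer.
#' @slot classes class labels in output order.
#' @export
setClass("NeuralModel", representation(
  spec = "ModelSpec", weights = "list", classes = "character"
))

#' Training history
#'
#' @slot trainLoss per-epoch training loss.
#' @slot valLoss per-epoch validation loss.
#' @slot valAcc per-epoch validation accuracy.
#' @slot bestEpoch epoch (1-based) attaining the minimum validation loss.
#' @export
setClass("TrainingHistory", representation(
  trainLoss = "numeric", valLoss = "numeric",
  valAcc = "numeric", bestEpoch = "integer"
))

setValidity("TrainingHistory", function(object) {
  n <- length(object@valLoss)
  if (length(object@trainLoss) != n || length(object@valAcc) != n)
    return("history vectors must align")
  if (n > 0L) {
    if (object@bestEpoch < 1L || object@bestEpoch > n)
      return("bestEpoch out of range")
    if (abs(object@valLoss[object@bestEpoch] - min(object@valLoss)) > 1e-12)
      return("bestEpoch must attain the minimum validation loss")
  }
  TRUE
})

#' Training configuration
#'
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot batchSize minibatch size (default 100).
#' @slot patience epochs without a new minimum validation loss before
#'   stopping (default 5).
#' @slot maxEpochs hard bound on epochs (default 500).
#' @slot seed RNG seed.
#' @slot classWeights optional named numeric vector of per-class loss weights.
#' @export
setClass("TrainingConfig", representation(
  learningRate = "numeric", batchSize = "integer", patience = "integer",
  maxEpochs = "integer", seed = "integer", classWeights = "numeric"
))

setValidity("TrainingConfig", function(object) {
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  TRUE
})

#' Multiclass confusion matrix
#'
#' Rows are true labels, columns predicted labels, in a frozen class order.
#'
#' @slot counts K x K integer matrix.
#' @slot classes class labels defining row/column order.
#' @export
setClass("ConfusionMatrix", representation(
  counts = "matrix", classes = "character"
))

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classes)
  if (!all(dim(object@counts) == c(k, k)))
    return("counts must be K x K for K classes")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' Evaluation report
#'
#' Per-class and macro precision/recall/F1 plus the multiclass Matthews
#' correlation coefficient, the confusion matrix and the set of correctly
#' classified ids.
#'
#' @slot perClass data.frame with columns class, precision, recall, f1.
#' @slot macroPrecision,macroRecall,macroF1 unweighted class means.
#' @slot mcc multiclass Matthews correlation coefficient.
#' @slot confusion the underlying \linkS4class{ConfusionMatrix}.
#' @slot correctIds ids of correctly classified records (may be empty when
#'   ids were not supplied).
#' @export
setClass("EvaluationReport", representation(
  perClass = "data.frame", macroPrecision = "numeric",
  macroRecall = "numeric", macroF1 = "numeric", mcc = "numeric",
  confusion = "ConfusionMatrix", correctIds = "character"
))

#' Benchmark harmonization rules
#'
#' @slot labelMap named character vector mapping source labels to target
#'   labels, with the sentinel \code{"DROP"} for labels absent from the
#'   harmonized scheme.
#' @slot maxLength maximum sequence length in nt (default 750).
#' @slot excludeMatureMirna drop miRNA records of mature length (<= 30 nt).
#' @slot similarityThreshold records with identity above this value to any
#'   reference (training) sequence are dropped (default 0.9).
#' @export
setClass("HarmonizationRules", representation(
  labelMap = "character", maxLength = "integer",
  excludeMatureMirna = "logical", similarityThreshold = "numeric"
))

#' Synthetic class profile
#'
#' Generative description of one ncRNA class: a length range, sequence
#' motifs (IUPAC pattern, insertion probability, positional preference) and
#' a structural template.
#'
#' @slot label class label.
#' @slot lengthRange integer vector \code{c(min, max)} in nt.
#' @slot motifs list of lists with elements \code{pattern}, \code{prob},
#'   \code{where} (one of \code{"5p"}, \code{"3p"}, \code{"center"},
#'   \code{"any"}).
#' @slot structureTemplate one of \code{"none"}, \code{"hairpin"},
#'   \code{"multi_stem"}.
#' @slot stemMismatchRate per-base mismatch rate in templated stems.
#' @export
setClass("ClassProfile", representation(
  label = "character", lengthRange = "integer", motifs = "list",
  structureTemplate = "character", stemMismatchRate = "numeric"
))

setValidity("ClassProfile", function(object) {
  if (object@lengthRange[1L] < 15L) return("minimum length must be >= 15")
  if (object@lengthRange[2L] > 11922L) return("maximum length must be <= 11922")
  if (object@lengthRange[1L] > object@lengthRange[2L])
    return("lengthRange must be ordered")
  if (object@stemMismatchRate < 0 || object@stemMismatchRate > 1)
    return("stemMismatchRate must be in [0, 1]")
  ok <- vapply(object@motifs, function(m)
    is.character(m$pattern) && m$prob >= 0 && m$prob <= 1, logical(1))
  if (length(ok) && !all(ok)) return("malformed motif entry")
  TRUE
})
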