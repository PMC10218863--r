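#' Number of trainable parameters
#'
#' For a \linkS4class{ModelSpec} the count is derived from the declared layer
#' shapes; for a \linkS4class{NeuralModel} it is the total length of the
#' realized weight arrays.  The two agree for every buildable spec.
#'
#' @param object a \linkS4class{ModelSpec} or \linkS4class{NeuralModel}.
#' @return integer parameter count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' Class-probability prediction
#'
#' @param object a \linkS4class{NeuralModel}.
#' @param x encoded inputs: an integer matrix (samples x positions) for
#'   convolutional models, a \code{dgCMatrix} for the graph model, or a list
#'   of both for the merged model (sequence first, graph second).
#' @param ... unused.
#' @return numeric matrix (samples x classes) of probabilities, rows summing
#'   to 1.
#' @export
setGeneric("predictProba", function(object, x, ...) standardGeneric("predictProba"))

#' @rdname ncRNASet-accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))
#' @rdname ncRNASet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname ncRNASet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname ncRNASet-accessors
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))
#' @rdname ncRNASet-accessors
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))
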