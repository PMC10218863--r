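.conv_block <- function(kernel, pool, filters = 64L, n_conv = 2L) {
  c(lapply(seq_len(n_conv), function(i)
      list(type = "conv", kernel = as.integer(kernel),
           filters = as.integer(filters), activation = "relu")),
    list(list(type = "maxpool", pool = as.integer(pool))))
}

.new_spec <- function(name, branches, n_classes) {
  new("ModelSpec", name = name, branches = branches,
      head = list(list(type = "dense", units = as.integer(n_classes),
                       activation = "softmax")),
      nClasses = as.integer(n_classes))
}

#' Graph-encoding classifier (GrEnc)
#'
#' A fully connected network on the hashed graph-feature vector: one dense
#' ReLU layer with 10 nodes followed by the softmax output layer.
#'
#' @param inputDim graph-vector dimension (default 32768).
#' @param nClasses number of output classes (6 general, 10 fine-grained).
#' @return a \linkS4class{ModelSpec}.
#' @examples
#' countParameters(buildGrEnc())  # 327756
#' @export
buildGrEnc <- function(inputDim = 32768L, nClasses = 6L) {
  stopifnot(inputDim > 0L)
  branch <- list(input = list(kind = "dense", dim = as.integer(inputDim)),
                 layers = list(list(type = "dense", units = 10L,
                                    activation = "relu")))
  .new_spec("GrEnc", list(branch), nClasses)
}

#' Sequence-encoding classifier (SeqEnc)
#'
#' A 1-D CNN on the ordinally encoded, padded primary sequence: a
#' 4-dimensional word embedding over the 17-token vocabulary, four
#' convolutional blocks (two length-preserving ReLU conv layers of 64
#' kernels each, then max pooling) with kernel sizes 3/7/11/17 and pool
#' sizes 4/4/2/2, 50\% dropout, flatten, a dense ReLU layer of 10 nodes and
#' the softmax output.
#'
#' @param vocab vocabulary size (default 17).
#' @param padTo padded input length (default 12000).
#' @param nClasses number of output classes.
#' @param embedDim embedding dimension.
#' @param filters kernels per convolutional layer.
#' @param kernelSizes kernel size per block.
#' @param poolSizes pool size per block.
#' @param nConv convolutional layers per block.
#' @param dropout dropout rate after the last block.
#' @param denseWidth width of the penultimate dense layer.
#' @return a \linkS4class{ModelSpec}.
#' @export
buildSeqEnc <- function(vocab = 17L, padTo = 12000L, nClasses = 6L,
                        embedDim = 4L, filters = 64L,
                        kernelSizes = c(3L, 7L, 11L, 17L),
                        poolSizes = c(4L, 4L, 2L, 2L),
                        nConv = 2L, dropout = 0.5, denseWidth = 10L) {
  stopifnot(length(kernelSizes) == length(poolSizes))
  layers <- list(list(type = "embedding", vocab = as.integer(vocab),
                      dim = as.integer(embedDim)))
  for (b in seq_along(kernelSizes))
    layers <- c(layers, .conv_block(kernelSizes[b], poolSizes[b],
                                    filters, nConv))
  layers <- c(layers,
              list(list(type = "dropout", rate = dropout),
                   list(type = "flatten"),
                   list(type = "dense", units = as.integer(denseWidth),
                        activation = "relu")))
  branch <- list(input = list(kind = "tokens", length = as.integer(padTo)),
                 layers = layers)
  .new_spec("SeqEnc", list(branch), nClasses)
}

#' Structure-encoding classifier (StrEnc)
#'
#' Identical to \code{\link{buildSeqEnc}} but over the 26-token combined
#' nucleotide-substructure alphabet and with kernel size 7 in all four
#' blocks.
#'
#' @inheritParams buildSeqEnc
#' @return a \linkS4class{ModelSpec}.
#' @export
buildStrEnc <- function(vocab = 26L, padTo = 12000L, nClasses = 6L,
                        embedDim = 4L, filters = 64L,
                        kernelSizes = rep(7L, 4L),
                        poolSizes = c(4L, 4L, 2L, 2L),
                        nConv = 2L, dropout = 0.5, denseWidth = 10L) {
  spec <- buildSeqEnc(vocab = vocab, padTo = padTo, nClasses = nClasses,
                      embedDim = embedDim, filters = filters,
                      kernelSizes = kernelSizes, poolSizes = poolSizes,
                      nConv = nConv, dropout = dropout,
                      denseWidth = denseWidth)
  spec@name <- "StrEnc"
  spec
}

#' Late-integration merged classifier (MncR)
#'
#' Runs the sequence branch and the graph branch in parallel, concatenates
#' their 10-node penultimate dense layers to one 20-node layer and applies a
#' single softmax output layer directly.  Weights are freshly initialized;
#' nothing is pre-assigned from the solo models.
#'
#' @param seqSpec a \linkS4class{ModelSpec} from \code{\link{buildSeqEnc}}
#'   (or \code{buildStrEnc}).
#' @param graphSpec a \linkS4class{ModelSpec} from \code{\link{buildGrEnc}}.
#' @param nClasses number of output classes (6 or 10).
#' @return a \linkS4class{ModelSpec} named \code{"MncR"}.
#' @export
buildMncR <- function(seqSpec = buildSeqEnc(), graphSpec = buildGrEnc(),
                      nClasses = 6L) {
  for (s in list(seqSpec, graphSpec)) {
    last <- s@branches[[1L]]$layers[[length(s@branches[[1L]]$layers)]]
    if (last$type != "dense" || last$units != 10L)
      stop("branch must end in a 10-node dense layer")
  }
  .new_spec("MncR", list(seqSpec@branches[[1L]], graphSpec@branches[[1L]]),
            nClasses)
}

#' Width of the merged concatenation layer
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return integer: the summed widths of the branch output layers (20 for
#'   the merged model, 10 for the solo models).
#' @export
mergeWidth <- function(spec) {
  sum(vapply(spec@branches, function(br) {
    last <- br$layers[[length(br$layers)]]
    as.integer(last$units)
  }, integer(1)))
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "ModelSpec", function(object) {
  total <- 0L
  for (br in object@branches)
    total <- total + .layer_param_count(br$input, br$layers)
  merged <- mergeWidth(object)
  total + .layer_param_count(list(kind = "dense", dim = merged), object@head)
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "NeuralModel", function(object) {
  count <- function(w) {
    if (is.list(w)) return(sum(vapply(w, count, numeric(1))))
    length(w)
  }
  as.integer(count(object@weights))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': %d branch(es), %d classes, %s parameters\n",
              object@name, length(object@branches), object@nClasses,
              format(countParameters(object), big.mark = ",")))
  invisible(object)
})

#' Realize a model specification
#'
#' Allocates and initializes all trainable weights (Glorot-uniform for dense
#' and convolutional layers, small-uniform for embeddings; embedding row 0 —
#' the padding token — is trainable like any other row).
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param classes class labels in output order; defaults to
#'   \code{class1..classK}.
#' @param seed RNG seed for the initialization.
#' @return a \linkS4class{NeuralModel}.
#' @export
initializeModel <- function(spec, classes = NULL, seed = 1L) {
  if (is.null(classes)) classes <- paste0("class", seq_len(spec@nClasses))
  if (length(classes) != spec@nClasses)
    stop("classes must match nClasses")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  branches <- lapply(spec@branches, function(br)
    .init_layers(br$input, br$layers))
  head <- .init_layers(list(kind = "dense", dim = mergeWidth(spec)),
                       spec@head)
  new("NeuralModel", spec = spec, weights = list(branches = branches,
                                                 head = head),
      classes = as.character(classes))
}

setMethod("show", "NeuralModel", function(object) {
  cat(sprintf("NeuralModel '%s': %s trainable parameters, classes: %s\n",
              object@spec@name,
              format(countParameters(object), big.mark = ","),
              paste(object@classes, collapse = ", ")))
  invisible(object)
})

.as_input_list <- function(model, x) {
  nb <- length(model@spec@branches)
  if (!is.list(x)) x <- list(x)
  if (length(x) != nb)
    stop(sprintf("model expects %d input(s), got %d", nb, length(x)))
  x
}

.model_forward <- function(model, xlist, training = FALSE) {
  spec <- model@spec
  outs <- vector("list", length(spec@branches))
  caches <- vector("list", length(spec@branches))
  B <- NULL
  for (b in seq_along(spec@branches)) {
    br <- spec@branches[[b]]
    fw <- .branch_forward(br$input, br$layers, model@weights$branches[[b]],
                          xlist[[b]], training = training)
    outs[[b]] <- fw$out
    caches[[b]] <- fw$cache
    B <- fw$B
  }
  merged <- do.call(cbind, outs)
  hw <- .branch_forward(list(kind = "dense", dim = ncol(merged)),
                        spec@head, model@weights$head, merged,
                        training = training)
  list(proba = hw$out, branch_caches = caches, head_cache = hw$cache,
       merged = merged, branch_outs = outs, B = B)
}

#' @rdname predictProba
#' @param batchSize samples per forward pass.
#' @export
setMethod("predictProba", "NeuralModel", function(object, x,
                                                  batchSize = 256L, ...) {
  xlist <- .as_input_list(object, x)
  n <- nrow(xlist[[1L]])
  out <- matrix(NA_real_, n, object@spec@nClasses,
                dimnames = list(rownames(xlist[[1L]]), object@classes))
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    sub <- lapply(xlist, function(m) m[idx, , drop = FALSE])
    out[idx, ] <- .model_forward(object, sub, training = FALSE)$proba
  }
  out
})

#' Predict class labels
#'
#' @param model a \linkS4class{NeuralModel}.
#' @param x encoded inputs (see \code{\link{predictProba}}).
#' @return character vector of predicted labels (argmax class).
#' @export
predictLabels <- function(model, x) {
  p <- predictProba(model, x)
  model@classes[max.col(p, ties.method = "first")]
}

#' Write predictions as TSV
#'
#' Columns: id, predicted label and one probability column per class.
#'
#' @param model a \linkS4class{NeuralModel}.
#' @param x encoded inputs.
#' @param ids record ids.
#' @param path output file; when NULL the data.frame is returned.
#' @return the prediction data.frame, invisibly when written.
#' @export
writePredictions <- function(model, x, ids, path = NULL) {
  p <- predictProba(model, x)
  df <- data.frame(id = ids,
                   predicted = model@classes[max.col(p, ties.method = "first")],
                   stringsAsFactors = FALSE)
  probs <- as.data.frame(p)
  names(probs) <- paste0("p_", gsub("[^A-Za-z0-9]", "_", model@classes))
  df <- cbind(df, probs)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Post-pooling temporal length
#'
#' The number of positions remaining after all pooling layers of a
#' convolutional branch (pooling uses floor division; convolutions preserve
#' length).  For the default 12,000-nt input and pools 4/4/2/2 this is 187.
#'
#' @param spec a \linkS4class{ModelSpec} with a tokens branch.
#' @param branch branch index.
#' @return integer temporal length.
#' @examples
#' pooledLength(buildSeqEnc())  # 187
#' @export
pooledLength <- function(spec, branch = 1L) {
  br <- spec@branches[[branch]]
  if (br$input$kind != "tokens") stop("branch has no temporal axis")
  L <- br$input$length
  for (ly in br$layers) if (ly$type == "maxpool") L <- L %/% ly$pool
  as.integer(L)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
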