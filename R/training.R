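#' Training configuration constructor
#'
#' Defaults follow the published protocol: Adam with learning rate 0.001,
#' batch size 100, categorical cross-entropy, early stopping after five
#' consecutive epochs without a new minimum validation loss, and the model
#' checkpointed at every new minimum (the returned model is the best, not
#' the last).  \code{maxEpochs} is a practical termination bound.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param maxEpochs hard epoch bound.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param classWeights optional named per-class loss weights.
#' @return a \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(learningRate = 0.001, batchSize = 100L,
                           patience = 5L, maxEpochs = 500L, seed = 1L,
                           classWeights = numeric(0)) {
  new("TrainingConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
      classWeights = classWeights)
}

#' Inverse-frequency class weights
#'
#' \code{weight_c = N / (K * n_c)} for \code{N} total samples, \code{K}
#' classes and \code{n_c} samples in class \code{c}; balanced data yields
#' all weights 1.
#'
#' @param labels character vector of class labels.
#' @param classes the declared class set; defaults to the labels present.
#' @return named numeric vector of weights.
#' @examples
#' computeClassWeights(rep(c("A", "B"), c(100, 50)))
#' @export
computeClassWeights <- function(labels, classes = sort(unique(labels))) {
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0L))
    stop(sprintf("class '%s' has no samples", names(counts)[counts == 0L][1L]))
  n <- length(labels)
  k <- length(classes)
  setNames(as.numeric(n / (k * counts)), classes)
}

#' Categorical cross-entropy
#'
#' @param proba samples x classes probability matrix.
#' @param labels true labels.
#' @param classes class order matching \code{proba} columns.
#' @param classWeights optional named per-class weights; the weighted loss
#'   is \code{sum(w_y * -log p_y) / n} and reduces to the unweighted loss
#'   when all weights are 1.
#' @param eps probability floor for numerical stability.
#' @return scalar loss.
#' @export
crossEntropyLoss <- function(proba, labels, classes = colnames(proba),
                             classWeights = NULL, eps = 1e-12) {
  yi <- match(labels, classes)
  if (anyNA(yi)) stop("label outside the class set")
  p <- pmax(proba[cbind(seq_len(nrow(proba)), yi)], eps)
  w <- if (is.null(classWeights) || !length(classWeights)) 1
       else unname(classWeights[labels])
  sum(w * -log(p)) / nrow(proba)
}

.one_hot <- function(labels, classes) {
  yi <- match(labels, classes)
  if (anyNA(yi))
    stop(sprintf("label '%s' outside the class set",
                 labels[which(is.na(yi))[1L]]))
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), yi)] <- 1
  y
}

#' Early-stopping trace
#'
#' Pure form of the stopping rule used by \code{\link{trainModel}}: a new
#' minimum validation loss (strict improvement; ties do not count) resets
#' the patience counter; training stops after \code{patience} consecutive
#' epochs without one.
#'
#' @param valLosses per-epoch validation losses as observed.
#' @param patience patience in epochs.
#' @return list with \code{stopEpoch} (last epoch run; \code{length(valLosses)}
#'   when the patience never triggers) and \code{bestEpoch}.
#' @examples
#' earlyStoppingTrace(c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44, 0.45), 5)
#' @export
earlyStoppingTrace <- function(valLosses, patience) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < best) {
      best <- valLosses[e]
      best_epoch <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience)
        return(list(stopEpoch = e, bestEpoch = best_epoch))
    }
  }
  list(stopEpoch = length(valLosses), bestEpoch = best_epoch)
}

#' Train a model
#'
#' Minibatch Adam on categorical cross-entropy with optional per-class loss
#' weights.  After every epoch the validation loss is computed (unweighted,
#' dropout inactive); whenever it improves on the previous minimum the
#' weights are checkpointed, and training stops after \code{patience}
#' consecutive epochs without improvement or at \code{maxEpochs}.  The
#' returned model carries the checkpointed best weights.
#'
#' @param spec a \linkS4class{ModelSpec} (or an already initialized
#'   \linkS4class{NeuralModel} to continue from).
#' @param x training inputs: integer matrix, \code{dgCMatrix}, or list of
#'   per-branch matrices for the merged model.
#' @param labels training labels.
#' @param valX,valLabels validation inputs and labels.
#' @param config a \linkS4class{TrainingConfig}.
#' @param classes class order; defaults to the sorted unique training
#'   labels.
#' @param verbose print per-epoch progress.
#' @return list with elements \code{model} (\linkS4class{NeuralModel}) and
#'   \code{history} (\linkS4class{TrainingHistory}).
#' @export
trainModel <- function(spec, x, labels, valX, valLabels,
                       config = trainingConfig(),
                       classes = sort(unique(labels)), verbose = FALSE) {
  xlist <- if (is.list(x)) x else list(x)
  vlist <- if (is.list(valX)) valX else list(valX)
  n <- nrow(xlist[[1L]])
  if (n == 0L || length(labels) == 0L) stop("empty training set")
  if (nrow(vlist[[1L]]) == 0L || length(valLabels) == 0L)
    stop("empty validation set")
  stopifnot(length(labels) == n)

  model <- if (is(spec, "NeuralModel")) spec
           else initializeModel(spec, classes = classes, seed = config@seed)
  classes <- model@classes
  Y <- .one_hot(labels, classes)
  .one_hot(valLabels, classes)  # validates the labels
  cw <- config@classWeights
  wvec <- if (length(cw)) {
    if (!all(classes %in% names(cw))) stop("classWeights must cover all classes")
    unname(cw[labels])
  } else rep(1, n)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config@seed + 1L)

  adam <- .adam_init(model@weights)
  t_step <- 0L
  best_val <- Inf
  best_weights <- model@weights
  best_epoch <- 0L
  wait <- 0L
  tr_loss <- val_loss <- val_acc <- numeric(0)

  for (epoch in seq_len(config@maxEpochs)) {
    perm <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq.int(1L, n, by = config@batchSize)) {
      idx <- perm[start:min(n, start + config@batchSize - 1L)]
      xb <- lapply(xlist, function(m) m[idx, , drop = FALSE])
      yb <- Y[idx, , drop = FALSE]
      wb <- wvec[idx]
      fw <- .model_forward(model, xb, training = TRUE)
      p <- pmax(fw$proba, 1e-12)
      batch_losses <- c(batch_losses,
                        sum(wb * -log(rowSums(p * yb))) / length(idx))
      dZ <- (fw$proba - yb) * (wb / length(idx))
      hgrads <- .branch_backward(list(kind = "dense", dim = ncol(fw$merged)),
                                 model@spec@head, model@weights$head,
                                 fw$head_cache, dZ, fw$B)
      # gradient wrt the merged layer
      lastW <- model@weights$head[[1L]]$W
      dmerged <- dZ %*% t(lastW)
      if (length(model@spec@head) > 1L)
        stop("multi-layer heads are not supported")
      bgrads <- vector("list", length(model@spec@branches))
      col0 <- 0L
      for (b in seq_along(model@spec@branches)) {
        br <- model@spec@branches[[b]]
        wdt <- ncol(fw$branch_outs[[b]])
        dout <- dmerged[, (col0 + 1L):(col0 + wdt), drop = FALSE]
        col0 <- col0 + wdt
        bgrads[[b]] <- .branch_backward(br$input, br$layers,
                                        model@weights$branches[[b]],
                                        fw$branch_caches[[b]], dout, fw$B)
      }
      t_step <- t_step + 1L
      res <- .adam_update(model@weights,
                          list(branches = bgrads, head = hgrads),
                          adam, config@learningRate, t_step)
      model@weights <- res$w
      adam <- res$s
    }

    vp <- predictProba(model, vlist)
    vl <- crossEntropyLoss(vp, valLabels, classes)
    va <- mean(classes[max.col(vp, ties.method = "first")] == valLabels)
    tr_loss <- c(tr_loss, mean(batch_losses))
    val_loss <- c(val_loss, vl)
    val_acc <- c(val_acc, va)
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f, acc %.3f",
                      epoch, mean(batch_losses), vl, va))
    if (vl < best_val) {
      best_val <- vl
      best_weights <- model@weights
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config@patience) break
    }
  }

  model@weights <- best_weights
  history <- new("TrainingHistory", trainLoss = tr_loss, valLoss = val_loss,
                 valAcc = val_acc, bestEpoch = as.integer(best_epoch))
  list(model = model, history = history)
}

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: %d epoch(s), best epoch %d (val loss %.4f)\n",
              length(object@valLoss), object@bestEpoch,
              if (length(object@valLoss)) object@valLoss[object@bestEpoch]
              else NA_real_))
  invisible(object)
})

#' Write a training history as TSV
#'
#' Columns: epoch, train_loss, val_loss, val_acc.
#'
#' @param history a \linkS4class{TrainingHistory}.
#' @param path output file; when NULL the data.frame is returned.
#' @return the data.frame, invisibly when written.
#' @export
writeHistory <- function(history, path = NULL) {
  df <- data.frame(epoch = seq_along(history@valLoss),
                   train_loss = history@trainLoss,
                   val_loss = history@valLoss,
                   val_acc = history@valAcc)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Balanced fold assignment
#'
#' Assigns every sample to one of \code{nFolds} folds so that, within each
#' class, fold sizes differ by at most one; the assignment is a partition
#' and is deterministic for a fixed seed.
#'
#' @param labels class labels.
#' @param nFolds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold indices in 1..nFolds.
#' @export
makeFolds <- function(labels, nFolds = 10L, seed = 1L) {
  counts <- table(labels)
  if (any(counts < nFolds))
    stop(sprintf("class '%s' has fewer than %d samples",
                 names(counts)[counts < nFolds][1L], nFolds))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Ten-fold cross-validation
#'
#' Splits the data into balanced folds (per-class counts differing by at
#' most one across folds), trains on nine folds and validates on the held
#' -out fold, once per fold, and reports the per-epoch median validation
#' loss across folds.  Folds that stopped early carry their last validation
#' loss forward so the median stays defined at every epoch.
#'
#' @param x inputs (matrix, \code{dgCMatrix} or list of per-branch
#'   matrices).
#' @param labels class labels.
#' @param specBuilder function returning a fresh \linkS4class{ModelSpec}.
#' @param config a \linkS4class{TrainingConfig}; fold \code{f} trains with
#'   seed \code{config@seed + f}.
#' @param nFolds number of folds (default 10).
#' @return list with \code{histories} (one \linkS4class{TrainingHistory}
#'   per fold), \code{medianValLoss} and \code{folds} (the assignment).
#' @export
tenFoldCV <- function(x, labels, specBuilder, config = trainingConfig(),
                      nFolds = 10L) {
  xlist <- if (is.list(x)) x else list(x)
  fold <- makeFolds(labels, nFolds, seed = config@seed)
  classes <- sort(unique(labels))
  histories <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    cfg <- config
    cfg@seed <- config@seed + f
    fit <- trainModel(specBuilder(),
                      lapply(xlist, function(m) m[tr, , drop = FALSE]),
                      labels[tr],
                      lapply(xlist, function(m) m[!tr, , drop = FALSE]),
                      labels[!tr],
                      cfg, classes = classes)
    histories[[f]] <- fit$history
  }
  max_e <- max(vapply(histories, function(h) length(h@valLoss), integer(1)))
  padded <- vapply(histories, function(h) {
    v <- h@valLoss
    c(v, rep(v[length(v)], max_e - length(v)))
  }, numeric(max_e))
  med <- apply(matrix(padded, nrow = max_e), 1L, median)
  list(histories = histories, medianValLoss = med, folds = fold)
}
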