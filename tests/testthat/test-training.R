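test_that("class weights are inverse-frequency normalized to mean one", {
  w <- computeClassWeights(rep(c("A", "B", "C"), each = 100))
  expect_equal(unname(w), c(1, 1, 1))
  w2 <- computeClassWeights(rep(c("A", "B"), c(100, 50)))
  expect_equal(w2[["A"]], 0.75)
  expect_equal(w2[["B"]], 1.5)
  expect_equal(unname(computeClassWeights(rep("A", 7))), 1)
  expect_error(computeClassWeights(rep("A", 5), classes = c("A", "B")),
               "no samples")
})

test_that("weighted cross-entropy reduces to the unweighted loss for unit weights", {
  set.seed(1)
  p <- matrix(runif(30), 10, 3)
  p <- p / rowSums(p)
  colnames(p) <- c("a", "b", "c")
  lab <- sample(c("a", "b", "c"), 10, TRUE)
  w1 <- setNames(rep(1, 3), c("a", "b", "c"))
  expect_equal(crossEntropyLoss(p, lab, classWeights = w1),
               crossEntropyLoss(p, lab), tolerance = 1e-7)
  expect_error(crossEntropyLoss(p, c(lab[-1], "d")), "outside")
})

test_that("early stopping follows the hand-traced protocol", {
  tr <- earlyStoppingTrace(c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44, 0.45), 5)
  expect_identical(tr$stopEpoch, 7L)
  expect_identical(tr$bestEpoch, 2L)
  # strictly decreasing: never triggers
  tr2 <- earlyStoppingTrace(seq(1, 0.1, length.out = 9), 5)
  expect_identical(tr2$stopEpoch, 9L)
  expect_identical(tr2$bestEpoch, 9L)
  # improvement after four flat epochs resets the counter
  tr3 <- earlyStoppingTrace(c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44, 0.39,
                              0.40, 0.41, 0.42, 0.43, 0.44), 5)
  expect_identical(tr3$stopEpoch, 12L)
  expect_identical(tr3$bestEpoch, 7L)
  # a tie is not an improvement
  tr4 <- earlyStoppingTrace(c(0.5, 0.5, 0.5, 0.5), 3)
  expect_identical(tr4$stopEpoch, 4L)
  expect_identical(tr4$bestEpoch, 1L)
})

make_toy_problem <- function(n = 90, d = 12, k = 3, seed = 8) {
  set.seed(seed)
  lab <- rep(letters[1:k], length.out = n)
  G <- matrix(abs(rnorm(n * d, sd = 0.1)), n, d)
  for (i in seq_len(n)) G[i, match(lab[i], letters) * 3] <- 2
  list(x = G, lab = lab)
}

test_that("training checkpoints the best model and stops on patience", {
  toy <- make_toy_problem()
  tr <- 1:60; va <- 61:90
  spec <- buildGrEnc(inputDim = 12, nClasses = 3)
  cfg <- trainingConfig(batchSize = 20, maxEpochs = 40, seed = 3)
  fit <- trainModel(spec, toy$x[tr, ], toy$lab[tr], toy$x[va, ],
                    toy$lab[va], cfg, classes = c("a", "b", "c"))
  h <- fit$history
  expect_lte(length(h@valLoss), 40L)
  expect_identical(h@bestEpoch, which.min(h@valLoss))
  # history is consistent with the pure stopping rule
  trace <- earlyStoppingTrace(h@valLoss, cfg@patience)
  expect_identical(length(h@valLoss), trace$stopEpoch)
  expect_identical(h@bestEpoch, trace$bestEpoch)
  # checkpointed model attains the minimum validation loss, not the last
  p <- predictProba(fit$model, toy$x[va, ])
  expect_equal(crossEntropyLoss(p, toy$lab[va], c("a", "b", "c")),
               min(h@valLoss), tolerance = 1e-10)
  expect_lte(min(h@valLoss), h@valLoss[length(h@valLoss)])
})

test_that("training is reproducible for a fixed seed and validates inputs", {
  toy <- make_toy_problem()
  tr <- 1:60; va <- 61:90
  spec <- buildGrEnc(inputDim = 12, nClasses = 3)
  cfg <- trainingConfig(batchSize = 30, maxEpochs = 8, patience = 8, seed = 9)
  f1 <- trainModel(spec, toy$x[tr, ], toy$lab[tr], toy$x[va, ],
                   toy$lab[va], cfg)
  f2 <- trainModel(spec, toy$x[tr, ], toy$lab[tr], toy$x[va, ],
                   toy$lab[va], cfg)
  expect_identical(f1$history@valLoss, f2$history@valLoss)
  expect_identical(f1$history@trainLoss, f2$history@trainLoss)
  expect_error(trainModel(spec, toy$x[0, , drop = FALSE], character(0),
                          toy$x[va, ], toy$lab[va], cfg), "empty training")
  expect_error(trainModel(spec, toy$x[tr, ], toy$lab[tr], toy$x[va, ],
                          rep("z", 30), cfg, classes = c("a", "b", "c")),
               "outside the class set")
})

test_that("fold assignment is a balanced partition", {
  lab <- rep(c("a", "b", "c", "d", "e", "f"), each = 100)
  fold <- makeFolds(lab, 10, seed = 2)
  expect_identical(length(fold), 600L)
  tab <- table(lab, fold)
  expect_true(all(tab == 10L))
  expect_identical(makeFolds(lab, 10, seed = 2), fold)
  # imbalance within one: 95 samples over 10 folds
  lab2 <- rep("a", 95)
  tab2 <- table(makeFolds(lab2, 10, seed = 1))
  expect_true(max(tab2) - min(tab2) <= 1)
  expect_error(makeFolds(rep("a", 5), 10), "fewer than")
})

test_that("cross-validation uses each fold once and reports the median curve", {
  toy <- make_toy_problem(n = 120, seed = 12)
  cv <- tenFoldCV(toy$x, toy$lab,
                  function() buildGrEnc(inputDim = 12, nClasses = 3),
                  trainingConfig(batchSize = 30, maxEpochs = 3, patience = 3,
                                 seed = 4),
                  nFolds = 10L)
  expect_length(cv$histories, 10L)
  expect_identical(sort(unique(cv$folds)), 1:10)
  max_e <- max(vapply(cv$histories, function(h) length(h@valLoss),
                      integer(1)))
  expect_length(cv$medianValLoss, max_e)
  # median at epoch 1 equals the plain median of the fold losses
  e1 <- vapply(cv$histories, function(h) h@valLoss[1L], numeric(1))
  expect_equal(cv$medianValLoss[1L], median(e1))
})
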