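test_that("confusion matrices count true rows against predicted columns", {
  cls <- c("a", "b", "c")
  cm <- confusion(rep(cls, each = 10), rep(cls, each = 10), cls)
  expect_identical(unname(diag(cm@counts)), rep(10L, 3))
  expect_identical(sum(cm@counts), 30L)
  cm2 <- confusion(rep(cls, each = 10), rep("a", 30), cls)
  expect_identical(unname(cm2@counts[, "a"]), rep(10L, 3))
  expect_identical(sum(cm2@counts[, -1]), 0L)
  expect_error(confusion(c("a", "q"), c("a", "a"), cls), "unknown true")
  expect_error(confusion(c("a", "a"), c("a", "q"), cls), "unknown predicted")
  expect_error(confusion(c("a"), c("a", "b"), cls), "equal length")
})

test_that("the row-normalized diagonal equals per-class recall", {
  set.seed(10)
  true <- sample(c("a", "b", "c"), 200, TRUE)
  pred <- ifelse(runif(200) < 0.7, true, sample(c("a", "b", "c"), 200, TRUE))
  cm <- confusion(true, pred, c("a", "b", "c"))
  rep_ <- scores(cm)
  expect_equal(unname(diag(rowNormalize(cm))), rep_@perClass$recall)
  # the rendering threshold blanks small cells but never alters counts
  rn <- rowNormalize(cm, threshold = 0.005)
  expect_true(all(is.na(rn) | rn >= 0.005))
  expect_identical(sum(cm@counts), 200L)
})

test_that("scores match the published identities on canonical matrices", {
  cls2 <- c("x", "y")
  ident <- confusion(rep(cls2, each = 5), rep(cls2, each = 5), cls2)
  r <- scores(ident)
  expect_equal(r@macroF1, 1)
  expect_equal(r@mcc, 1)
  allwrong <- confusion(rep(cls2, each = 10),
                        rep(rev(cls2), each = 10), cls2)
  expect_equal(scores(allwrong)@mcc, -1)
  cm3 <- new("ConfusionMatrix",
             counts = matrix(c(8L, 1L, 0L, 2L, 9L, 3L, 0L, 0L, 7L), 3, 3,
                             dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c"))),
             classes = c("a", "b", "c"))
  r3 <- scores(cm3)
  o3 <- oracle_scores(cm3@counts)
  expect_equal(r3@macroF1, mean(o3$f1), tolerance = 1e-10)
  expect_equal(r3@mcc, o3$mcc, tolerance = 1e-10)
  expect_error(scores(confusion(character(0), character(0), "a")),
               "empty")
})

test_that("multiclass scoring agrees with the indicator-correlation oracle", {
  set.seed(21)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    cm <- random_confusion(k)
    if (sum(cm) == 0) cm[1, 1] <- 1L
    obj <- new("ConfusionMatrix", counts = cm, classes = letters[1:k])
    r <- scores(obj)
    o <- oracle_scores(cm)
    expect_equal(r@perClass$precision, o$precision, tolerance = 1e-10)
    expect_equal(r@perClass$recall, o$recall, tolerance = 1e-10)
    expect_equal(r@perClass$f1, o$f1, tolerance = 1e-10)
    expect_equal(r@mcc, o$mcc, tolerance = 1e-10)
  }
})

test_that("two-class MCC reduces to the classical binary formula", {
  set.seed(22)
  for (i in 1:50) {
    cm <- random_confusion(2)
    if (sum(cm) == 0) cm[1, 1] <- 1L
    obj <- new("ConfusionMatrix", counts = cm, classes = c("pos", "neg"))
    expect_equal(scores(obj)@mcc,
                 oracle_binary_mcc(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("scores are invariant under a simultaneous class permutation", {
  set.seed(23)
  cm <- random_confusion(4)
  obj <- new("ConfusionMatrix", counts = cm, classes = letters[1:4])
  perm <- c(3L, 1L, 4L, 2L)
  obj_p <- new("ConfusionMatrix", counts = cm[perm, perm],
               classes = letters[1:4][perm])
  r <- scores(obj); rp <- scores(obj_p)
  expect_equal(r@macroF1, rp@macroF1, tolerance = 1e-12)
  expect_equal(r@mcc, rp@mcc, tolerance = 1e-12)
  expect_equal(r@perClass$f1[perm], rp@perClass$f1, tolerance = 1e-12)
})

test_that("empty classes are excluded from the macro mean, not counted as zero", {
  cm <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm[1, 1] <- 5L; cm[2, 2] <- 5L  # class c never occurs
  obj <- new("ConfusionMatrix", counts = cm, classes = letters[1:3])
  expect_equal(scores(obj)@macroF1, 1)
})

test_that("micro accuracy equals the trace share and the correct-id share", {
  set.seed(24)
  ids_ <- sprintf("s%03d", 1:150)
  true <- sample(c("a", "b", "c"), 150, TRUE)
  pred <- ifelse(runif(150) < 0.6, true, sample(c("a", "b", "c"), 150, TRUE))
  r <- evaluatePredictions(true, pred, c("a", "b", "c"), ids = ids_)
  acc_trace <- sum(diag(r@confusion@counts)) / sum(r@confusion@counts)
  expect_equal(acc_trace, length(r@correctIds) / 150)
  expect_setequal(r@correctIds, ids_[true == pred])
})

test_that("overlap regions partition the universe", {
  u5 <- paste0("i", 1:5)
  ov <- overlapSets(list(A = u5, B = u5), u5)
  expect_identical(unname(ov["A&B"]), 5L)
  expect_identical(unname(ov["A"] + ov["B"] + ov["none"]), 0L)
  u3 <- c("a", "b", "c")
  ov2 <- overlapSets(list(A = "a", B = "b"), u3)
  expect_identical(unname(ov2[c("A", "B", "none", "A&B")]),
                   c(1L, 1L, 1L, 0L))
  # four sets against per-id enumeration
  set.seed(25)
  u <- paste0("x", 1:20)
  sets <- lapply(1:4, function(i) sample(u, sample(0:20, 1)))
  names(sets) <- LETTERS[1:4]
  ov4 <- overlapSets(sets, u)
  expect_identical(sum(ov4), 20L)
  # brute-force per-id region assignment
  for (id in u) {
    memb <- vapply(sets, function(s) id %in% s, logical(1))
    key <- if (any(memb)) paste(names(sets)[memb], collapse = "&") else "none"
    expect_gte(ov4[[key]], 1L)
  }
  expect_error(overlapSets(list(A = "zz"), u), "outside the universe")
})

make_benchmark_fixture <- function() {
  labs <- c("tRNA", "CD-Box", "HACA-Box", "scaRNA", "5S rRNA", "5.8S rRNA",
            "miRNA", "Ribozyme", "Riboswitch", "IRES", "tRNA", "miRNA")
  lens <- c(75, 90, 130, 200, 120, 155, 70, 100, 90, 300, 900, 80)
  set.seed(31)
  NcRNASet(id = sprintf("bm%02d", 1:12),
           sequence = vapply(lens, random_rna, character(1)),
           label = labs)
}

test_that("harmonization applies the drop, length and label-merging rules", {
  recs <- make_benchmark_fixture()
  pred <- setNames(c("tRNA", "HACA-Box", "CD-Box", "snoRNA", "rRNA",
                     "5S rRNA", "Riboswitch", "tRNA", "tRNA", "tRNA",
                     "tRNA", "miRNA"), ids(recs))
  h <- harmonize(recs, pred, defaultHarmonizationRules())
  # Ribozyme/Riboswitch/IRES dropped; the 900-nt tRNA exceeds 750 nt
  expect_setequal(h$id, sprintf("bm%02d", c(1:7, 12)))
  # CD-Box predicted as HACA-Box counts as correct (both map to snoRNA)
  expect_true(h$correct[h$id == "bm02"])
  expect_true(h$correct[h$id == "bm03"])
  # a prediction outside the shared scheme is incorrect
  expect_false(h$correct[h$id == "bm07"])
  expect_identical(h$predicted[h$id == "bm07"], "(invalid)")
  # all surviving labels are in the 4-class scheme
  expect_true(all(h$true %in% c("miRNA", "rRNA", "snoRNA", "tRNA")))
  expect_error(harmonize(recs, setNames(rep("piRNA", 12), ids(recs))),
               "unmapped")
})

test_that("harmonization is idempotent and screens near-duplicates", {
  recs <- make_benchmark_fixture()
  pred <- setNames(rep("tRNA", 12), ids(recs))
  h1 <- harmonize(recs, pred)
  recs2 <- NcRNASet(h1$id,
                    unname(sequences(recs)[h1$id]),
                    h1$true)
  pred2 <- setNames(h1$predicted, h1$id)
  h2 <- harmonize(recs2, pred2)
  expect_identical(h2$id, h1$id)
  expect_identical(h2$correct, h1$correct)
  # similarity screen: a record nearly identical to a training sequence is
  # excluded
  ref <- NcRNASet("train1", unname(sequences(recs)["bm01"]), "tRNA")
  h3 <- harmonize(recs, pred, reference = ref)
  expect_false("bm01" %in% h3$id)
  expect_true("bm02" %in% h3$id)
})

test_that("harmonization rules load from a YAML map", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("label_map:", "  tRNA: tRNA", "  Ribozyme: DROP",
               "max_length: 600", "similarity_threshold: 0.8"), y)
  rules <- readHarmonizationRules(y)
  expect_identical(rules@maxLength, 600L)
  expect_equal(rules@similarityThreshold, 0.8)
  expect_identical(unname(rules@labelMap[c("tRNA", "Ribozyme")]),
                   c("tRNA", "DROP"))
  # omitted fields keep the defaults
  y2 <- tempfile(fileext = ".yaml")
  writeLines("max_length: 500", y2)
  expect_identical(readHarmonizationRules(y2)@labelMap,
                   defaultHarmonizationRules()@labelMap)
})

test_that("mature-length miRNAs are excluded when the rules say so", {
  recs <- make_benchmark_fixture()
  pred <- setNames(rep("miRNA", 12), ids(recs))
  h <- harmonize(recs, pred)
  expect_true("bm07" %in% h$id)  # 70-nt miRNA stays (precursor length)
  short_mir <- NcRNASet("m1", random_rna(22), "miRNA")
  h2 <- harmonize(short_mir, c(m1 = "miRNA"))
  expect_identical(nrow(h2), 0L)
})
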