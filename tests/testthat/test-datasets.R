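write_fixture_fasta <- function(records, dir = tempfile()) {
  dir.create(dir)
  fa <- file.path(dir, "seqs.fa")
  tsv <- file.path(dir, "labels.tsv")
  writeLabeledFasta(records, fa, tsv)
  list(fasta = fa, labels = tsv)
}

test_that("labeled FASTA reading normalizes case and validates ids", {
  fx <- write_fixture_fasta(make_tiny_set())
  set <- readLabeledFasta(fx$fasta, fx$labels)
  expect_identical(length(set), 3L)
  expect_identical(unname(sequences(set)["r1"]), "GGGGAAAACCCC")
  # lowercase input is uppercased
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgu"), fa2)
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "x\tmiRNA"), tsv2)
  expect_identical(unname(sequences(readLabeledFasta(fa2, tsv2))), "ACGU")
  # duplicate FASTA id
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU", ">x", "GGCC"), fa3)
  expect_error(readLabeledFasta(fa3, tsv2), "duplicate")
  # missing label
  fa4 <- tempfile(fileext = ".fa")
  writeLines(c(">y", "ACGU"), fa4)
  expect_error(readLabeledFasta(fa4, tsv2), "missing label")
})

test_that("length filter keeps both boundaries inclusive", {
  set <- NcRNASet(paste0("s", 1:4),
                  c(strrep("A", 10), strrep("A", 15),
                    strrep("A", 11922), strrep("A", 12000)),
                  "lncRNA")
  kept <- lengthFilter(set)
  expect_identical(seqLengths(kept), c(15L, 11922L))
  expect_identical(length(lengthFilter(set[0])), 0L)
  expect_identical(ids(lengthFilter(kept)), ids(kept))
})

test_that("miRNA length classes follow the mature/precursor thresholds", {
  expect_identical(assignMirnaLengthClass(22), "mature")
  expect_identical(assignMirnaLengthClass(100), "precursor")
  expect_identical(assignMirnaLengthClass(35), "excluded")
  expect_identical(assignMirnaLengthClass(c(30, 31, 39, 40)),
                   c("mature", "excluded", "excluded", "precursor"))
})

test_that("greedy clustering removes near-duplicates above 90 percent identity", {
  s <- NcRNASet(c("a", "b"), c("AAAACCCCGGGG", "AAAACCCCGGGG"), "tRNA")
  expect_identical(length(clusterReduce(s)), 1L)
  # no shared 7-mers, dissimilar: both stay
  s2 <- NcRNASet(c("a", "b"), c("AAAACCCCGGGG", "UUUUAGCAUCGA"), "tRNA")
  expect_identical(length(clusterReduce(s2)), 2L)
  # one mismatch in 100 nt (99% identity) collapses to one representative
  set.seed(3)
  base <- random_rna(100)
  mut <- base
  substr(mut, 50, 50) <- setdiff(c("A", "C", "G", "U"),
                                 substr(base, 50, 50))[1]
  s3 <- NcRNASet(c("a", "b"), c(base, mut), "tRNA")
  red <- clusterReduce(s3)
  expect_identical(length(red), 1L)
  expect_gt(sequenceIdentity(base, mut), 0.9)
  # longest-first: the longer sequence is kept as representative
  s4 <- NcRNASet(c("short", "long"),
                 c(substr(base, 1, 80), base), "tRNA")
  expect_identical(ids(clusterReduce(s4)), "long")
  expect_error(clusterReduce(s4[0]), "non-empty")
})

test_that("identity against a reference set screens near-duplicates", {
  set.seed(5)
  ref <- NcRNASet("ref1", random_rna(80), "tRNA")
  near <- sequences(ref)[[1]]
  substr(near, 10, 10) <- "A"
  far <- random_rna(80)
  q <- NcRNASet(c("q1", "q2"), c(near, far), "tRNA")
  sim <- maxIdentityTo(q, ref)
  expect_gt(sim[1], 0.9)
  expect_lt(sim[2], 0.9)
})

test_that("splits are balanced partitions with the 90/10 rule", {
  set.seed(9)
  recs <- NcRNASet(
    id = sprintf("%s_%03d", rep(c("x", "y", "z"), each = 120), 1:120),
    sequence = replicate(360, random_rna(30)),
    label = rep(c("lncRNA", "tRNA", "snRNA"), each = 120))
  sp <- makeSplit(recs, perClassTotal = 120, testPerClass = 20, seed = 4)
  expect_identical(as.integer(table(classLabels(sp$test))), rep(20L, 3))
  expect_identical(as.integer(table(classLabels(sp$train))), rep(90L, 3))
  expect_identical(as.integer(table(classLabels(sp$validation))), rep(10L, 3))
  all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, ids(recs))
  sp2 <- makeSplit(recs, perClassTotal = 120, testPerClass = 20, seed = 4)
  expect_identical(ids(sp2$test), ids(sp$test))
  expect_error(makeSplit(recs, 120, 200, seed = 1), "fewer records")
  w <- testthat::capture_warnings(makeSplit(recs, 500, 20, seed = 1))
  expect_true(any(grepl("available", w)))
})

test_that("fine-grained relabeling expands and coarsens consistently", {
  recs <- NcRNASet(
    id = paste0("r", 1:6),
    sequence = c(strrep("A", 120), strrep("A", 22), strrep("A", 100),
                 strrep("A", 80), strrep("A", 150), strrep("A", 90)),
    label = c("rRNA", "miRNA", "miRNA", "tRNA", "snoRNA", "snoRNA"),
    subtype = c("5S", NA, NA, NA, "H/ACA-Box", "C/D-Box"))
  fine <- relabelFineGrained(recs)
  expect_identical(classLabels(fine),
                   c("short rRNA", "mature miRNA", "precursor miRNA",
                     "tRNA", "H/ACA-Box", "C/D-Box"))
  expect_identical(coarsenLabels(classLabels(fine)), classLabels(recs))
  long_r <- NcRNASet("r7", strrep("A", 2000), "rRNA", "28S")
  expect_identical(classLabels(relabelFineGrained(long_r)), "long rRNA")
  bad <- NcRNASet("r8", strrep("A", 100), "snoRNA")
  expect_error(relabelFineGrained(bad), "unknown subtype")
  bad2 <- NcRNASet("r9", strrep("A", 100), "rRNA", "Mitochondrial (mt)")
  expect_error(relabelFineGrained(bad2), "unknown subtype")
})
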