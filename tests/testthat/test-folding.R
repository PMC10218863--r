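test_that("base-pair maximization reproduces known optima and edge cases", {
  expect_identical(foldMFE("GGGGAAAACCCC"), "((((....))))")
  expect_identical(foldMFE("AAAAA"), ".....")
  expect_identical(foldMFE(""), "")
  # T pairs like U; lowercase input accepted
  expect_identical(foldMFE("ggggaaaacccc"), "((((....))))")
  expect_identical(count_pairs(foldMFE("GGGGTTTTCCCC")),
                   count_pairs(foldMFE("GGGGUUUUCCCC")))
  # ambiguity codes are unpairable
  expect_identical(foldMFE("NNNNNNNNNNNN"), "............")
  expect_error(foldMFE("ACGX"), "non-IUPAC")
  # determinism
  s <- random_rna(40)
  expect_identical(foldMFE(s), foldMFE(s))
})

test_that("builtin folding matches an independent dynamic program and full enumeration", {
  set.seed(42)
  for (i in 1:40) {
    s <- random_rna(sample(8:20, 1))
    db <- foldMFE(s)
    expect_true(oracle_structure_valid(s, db))
    expect_identical(count_pairs(db), as.integer(oracle_max_pairs(s)))
  }
  # exhaustive enumeration on very short sequences
  set.seed(7)
  for (i in 1:15) {
    s <- random_rna(sample(6:12, 1))
    expect_identical(count_pairs(foldMFE(s)),
                     as.integer(oracle_enum_max_pairs(s)))
  }
})

test_that("window shift is floor(window * fraction) with a minimum of 1", {
  expect_identical(computeShift(150, 0.25), 37L)
  expect_identical(computeShift(100, 0.25), 25L)
  expect_identical(computeShift(10, 0.05), 1L)
})

test_that("windowed shreps tile the sequence with full-width windows", {
  expect_identical(windowedShreps(random_rna(100))@offsets, 0L)
  expect_identical(windowedShreps(random_rna(150))@offsets, 0L)
  set.seed(5)
  expect_identical(windowedShreps(random_rna(200))@offsets, c(0L, 37L, 50L))
  expect_error(windowedShreps(""), "empty")
  # tiling property: the union of windows covers [0, length)
  for (len in c(151, 187, 300, 423)) {
    ss <- windowedShreps(random_rna(len))
    covered <- rep(FALSE, len)
    for (o in ss@offsets) covered[(o + 1):min(len, o + ss@windowSize)] <- TRUE
    expect_true(all(covered))
    expect_true(all(diff(ss@offsets) > 0))
    expect_identical(ss@offsets[length(ss@offsets)],
                     as.integer(len - ss@windowSize))
  }
})

test_that("shrep generation yields up to nShreps distinct structures per window", {
  set.seed(11)
  s <- random_rna(80)
  ss <- windowedShreps(s, foldingConfig(nShreps = 3L))
  reps <- ss@structures[[1L]]
  expect_lte(length(reps), 3L)
  expect_identical(anyDuplicated(reps), 0L)
  expect_identical(reps[1L], foldMFE(s))
  # every representative is a valid structure for the window
  for (db in reps) expect_true(oracle_structure_valid(s, db))
  # deterministic
  ss2 <- windowedShreps(s, foldingConfig(nShreps = 3L))
  expect_identical(ss@structures, ss2@structures)
})

test_that("substructure annotation assigns the six states by loop context", {
  expect_identical(annotateStructure("GGGGAAAACCCC", "((((....))))"),
                   "SSSSHHHHSSSS")
  expect_identical(annotateStructure("AAGGGGAAAACCCCAA", "..((((....)))).."),
                   "FFSSSSHHHHSSSSTT")
  expect_identical(annotateStructure("ACGU", "...."), "FFFF")
  # internal loop / bulge
  expect_identical(annotateStructure(strrep("A", 16), "((..((....))..))"),
                   "SSIISSHHHHSSIISS")
  # multi-loop: two helices branch from the closing pair
  db <- "((..((...))..((...))..))"
  ann <- annotateStructure(strrep("A", nchar(db)), db)
  expect_identical(ann, "SSMMSSHHHSSMMSSHHHSSMMSS")
  # external segment between two top-level stems is M
  db2 <- "((...))..((...))"
  ann2 <- annotateStructure(strrep("A", nchar(db2)), db2)
  expect_identical(ann2, "SSHHHSSMMSSHHHSS")
  expect_error(annotateStructure("ACG", "...."), "length")
})

test_that("annotation is length-preserving and marks exactly the paired positions S", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_rna(sample(10:60, 1))
    db <- foldMFE(s)
    ann <- annotateStructure(s, db)
    expect_identical(nchar(ann), nchar(s))
    expect_identical(sum(strsplit(ann, "")[[1L]] == "S"),
                     2L * count_pairs(db))
    expect_true(all(strsplit(ann, "")[[1L]] %in%
                    c("F", "T", "S", "M", "H", "I")))
  }
})

test_that("dot-bracket parsing rejects malformed strings", {
  expect_error(pairTable("(()"), "unbalanced")
  expect_error(pairTable("())"), "unbalanced")
  expect_error(pairTable("(.x)"), "invalid")
  expect_identical(pairTable("(...)"), c(5L, 0L, 0L, 0L, 1L))
})

test_that("structures serialize in Vienna style and shreps as TSV", {
  tmp <- tempfile(fileext = ".db")
  writeDotBracket("x", "GGGGAAAACCCC", "((((....))))", tmp)
  expect_identical(readLines(tmp),
                   c(">x", "GGGGAAAACCCC", "((((....))))"))
  ss <- windowedShreps(random_rna(200))
  tsv <- tempfile(fileext = ".tsv")
  writeShrepsTSV("x", ss, tsv)
  df <- read.delim(tsv)
  expect_identical(names(df), c("id", "offset", "structure"))
  expect_identical(sort(unique(df$offset)), c(0L, 37L, 50L))
})
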