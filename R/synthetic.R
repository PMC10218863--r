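.IUPAC <- list(A = "A", C = "C", G = "G", U = "U", T = "U",
               R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"),
               W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
               B = c("C", "G", "U"), D = c("A", "G", "U"),
               H = c("A", "C", "U"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "U"))

.RC <- c(A = "U", C = "G", G = "C", U = "A")

.rand_rna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s, mismatch_rate = 0) {
  ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
  out <- unname(.RC[ch])
  if (mismatch_rate > 0) {
    flip <- runif(length(out)) < mismatch_rate
    if (any(flip))
      out[flip] <- vapply(out[flip], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
  }
  paste(out, collapse = "")
}

.sample_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(b) {
    opts <- .IUPAC[[b]]
    if (is.null(opts)) stop(sprintf("invalid IUPAC symbol '%s'", b))
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.motif <- function(pattern, prob = 1, where = "any") {
  list(pattern = pattern, prob = prob, where = where)
}

#' Class-profile constructor
#'
#' @param label class label.
#' @param lengthRange \code{c(min, max)} in nt.
#' @param motifs list of motif descriptions (\code{pattern}, \code{prob},
#'   \code{where}).
#' @param structureTemplate \code{"none"}, \code{"hairpin"} or
#'   \code{"multi_stem"}.
#' @param stemMismatchRate per-base mismatch rate in templated stems.
#' @return a \linkS4class{ClassProfile}.
#' @export
classProfile <- function(label, lengthRange, motifs = list(),
                         structureTemplate = "none",
                         stemMismatchRate = 0.1) {
  new("ClassProfile", label = label,
      lengthRange = as.integer(lengthRange), motifs = motifs,
      structureTemplate = structureTemplate,
      stemMismatchRate = stemMismatchRate)
}

setMethod("show", "ClassProfile", function(object) {
  cat(sprintf("ClassProfile '%s': %d-%d nt, %d motif(s), template %s\n",
              object@label, object@lengthRange[1L], object@lengthRange[2L],
              length(object@motifs), object@structureTemplate))
  invisible(object)
})

# conserved rRNA-like blocks (synthetic constants, fixed for reproducibility)
.RRNA_BLOCKS <- c(
  "GGAUCACCUCCUUUCUAAGGAGUCAGGAUAGCGCAGCGGU",
  "CCGUAGGGAAACCUGCGGCUGGAUCACCUCCUAGUCGGAA",
  "GAAUUGCAGAACUCCGUGAACCAUCGAGUCUUUGAACGCA")

#' Default synthetic class profiles
#'
#' Six profiles emulating the heterogeneity of the ncRNA classes in length,
#' conserved motifs and structure content: mature-miRNA-like (20-24 nt,
#' 5' seed motif), precursor-miRNA-like (60-120 nt, hairpin with mismatched
#' arms and a seed motif in the 5' arm), tRNA-like (70-90 nt, four designed
#' stems plus a T-loop motif), snoRNA-like (70-250 nt, C box RUGAUGA and D
#' box CUGA), snRNA-like (100-300 nt, Sm site AAUUUUUGG), lncRNA-like
#' (200-4000 nt, motif-free) and rRNA-like (1400-3000 nt, three conserved
#' blocks).  With \code{fineGrained = TRUE} the miRNA, rRNA and snoRNA
#' classes split into their 10-class subtypes.
#'
#' @param fineGrained return the 10-class profile list.
#' @param capLength optional maximum length in nt: the long classes
#'   (lncRNA, rRNA) are capped for desk-scale runs (lncRNA to
#'   \code{(200, capLength)}, rRNA to \code{(300, capLength)}), matching a
#'   reduced \code{padTo}.
#' @return list of \linkS4class{ClassProfile} objects.
#' @export
defaultProfiles <- function(fineGrained = FALSE, capLength = NULL) {
  lnc_range <- c(200L, 4000L)
  rrna_range <- c(1400L, 3000L)
  if (!is.null(capLength)) {
    # truncated long molecules accumulate near the cap, so the capped rRNA
    # range hugs it while lncRNA keeps its broad spread
    lnc_range <- c(200L, as.integer(capLength))
    rrna_range <- c(as.integer(0.8 * capLength), as.integer(capLength))
  }
  mature <- classProfile("miRNA", c(20L, 24L),
                         motifs = list(.motif("UGAGGUAG", 1, "5p")))
  precursor <- classProfile("miRNA", c(60L, 120L),
                            motifs = list(.motif("UGAGGUAG", 1, "5p")),
                            structureTemplate = "hairpin")
  trna <- classProfile("tRNA", c(70L, 90L),
                       motifs = list(.motif("GUUCGAUU", 1, "3p")),
                       structureTemplate = "multi_stem")
  sno_cd <- classProfile("snoRNA", c(70L, 120L),
                         motifs = list(.motif("RUGAUGA", 1, "5p"),
                                       .motif("CUGA", 1, "3p")))
  sno_haca <- classProfile("snoRNA", c(120L, 160L),
                           motifs = list(.motif("ANANNA", 1, "center"),
                                         .motif("ACANNN", 1, "3p")))
  sca <- classProfile("snoRNA", c(200L, 300L),
                      motifs = list(.motif("RUGAUGA", 1, "5p"),
                                    .motif("ACANNN", 1, "3p")))
  snrna <- classProfile("snRNA", c(100L, 300L),
                        motifs = list(.motif("AAUUUUUGG", 1, "center")))
  lnc <- classProfile("lncRNA", lnc_range)
  rrna_long <- classProfile("rRNA", rrna_range,
                            motifs = list(.motif(.RRNA_BLOCKS[1L], 1, "5p"),
                                          .motif(.RRNA_BLOCKS[2L], 1, "center"),
                                          .motif(.RRNA_BLOCKS[3L], 1, "3p")))
  if (!fineGrained) {
    sno <- classProfile("snoRNA", c(70L, 250L),
                        motifs = list(.motif("RUGAUGA", 1, "5p"),
                                      .motif("CUGA", 1, "3p")))
    mir <- classProfile("miRNA", c(20L, 24L),
                        motifs = list(.motif("UGAGGUAG", 1, "5p")))
    # the general miRNA class mixes mature and precursor records 50/50
    return(list(mature_miRNA = mir, precursor_miRNA = precursor,
                tRNA = trna, snoRNA = sno, snRNA = snrna,
                lncRNA = lnc, rRNA = rrna_long))
  }
  short_range <- c(110L, 160L)
  rrna_short <- classProfile("short rRNA", short_range,
                             motifs = list(.motif(.RRNA_BLOCKS[1L], 1,
                                                  "center")))
  relab <- function(p, lab) { p@label <- lab; p }
  list(`mature miRNA` = relab(mature, "mature miRNA"),
       `precursor miRNA` = relab(precursor, "precursor miRNA"),
       tRNA = trna,
       `C/D-Box` = relab(sno_cd, "C/D-Box"),
       `H/ACA-Box` = relab(sno_haca, "H/ACA-Box"),
       scaRNA = relab(sca, "scaRNA"),
       snRNA = snrna,
       lncRNA = lnc,
       `short rRNA` = rrna_short,
       `long rRNA` = relab(rrna_long, "long rRNA"))
}

#' Apply YAML profile overrides
#'
#' The file maps profile list names to fields to override:
#' \code{length_range} (two integers), \code{motifs} (list of
#' \code{pattern}/\code{prob}/\code{where} maps), \code{structure_template}
#' and \code{stem_mismatch_rate}.  Profiles not mentioned pass through.
#'
#' @param profiles list of \linkS4class{ClassProfile} objects.
#' @param path YAML file with overrides.
#' @return the modified profile list.
#' @export
applyProfileOverrides <- function(profiles, path) {
  y <- yaml::read_yaml(path)
  for (nm in names(y)) {
    if (!nm %in% names(profiles))
      stop(sprintf("override for unknown profile '%s'", nm))
    ov <- y[[nm]]
    p <- profiles[[nm]]
    if (!is.null(ov$length_range))
      p@lengthRange <- as.integer(unlist(ov$length_range))
    if (!is.null(ov$motifs))
      p@motifs <- lapply(ov$motifs, function(m)
        .motif(m$pattern, m$prob %||% 1, m$where %||% "any"))
    if (!is.null(ov$structure_template))
      p@structureTemplate <- ov$structure_template
    if (!is.null(ov$stem_mismatch_rate))
      p@stemMismatchRate <- as.numeric(ov$stem_mismatch_rate)
    validObject(p)
    profiles[[nm]] <- p
  }
  profiles
}

#' Remove the sequence motifs from selected profiles
#'
#' Convenience for structure-dominated experiments: drops all motifs from
#' the profiles whose list names match, keeping the structure templates.
#'
#' @param profiles list of \linkS4class{ClassProfile} objects.
#' @param names_ profile list names to strip.
#' @return the modified profile list.
#' @export
stripMotifs <- function(profiles, names_) {
  for (nm in intersect(names_, names(profiles)))
    profiles[[nm]]@motifs <- list()
  profiles
}

.template_hairpin <- function(len, mismatch_rate) {
  loop <- 6L
  arm <- (len - loop) %/% 2L
  extra <- len - loop - 2L * arm
  left <- .rand_rna(arm)
  paste0(left, .rand_rna(loop), .revcomp(left, mismatch_rate),
         .rand_rna(extra))
}

.template_multistem <- function(len, mismatch_rate) {
  hp <- function(stem, loop)
    paste0(s <- .rand_rna(stem), .rand_rna(loop), .revcomp(s, mismatch_rate))
  acc <- .rand_rna(7L)
  core <- paste0(acc, "UU", hp(4L, 8L), hp(5L, 7L))
  tail_ <- paste0(hp(5L, 7L), .revcomp(acc, mismatch_rate), "ACCA")
  linker <- max(0L, len - nchar(core) - nchar(tail_) - 1L)
  out <- paste0(core, .rand_rna(linker + 1L), tail_)
  substr(out, 1L, len)  # trim if the drawn length is below the core size
}

.place_motif <- function(sequence, motif) {
  if (runif(1) > motif$prob) return(sequence)
  inst <- .sample_iupac(motif$pattern)
  n <- nchar(sequence)
  w <- nchar(inst)
  if (w > n) return(sequence)
  start <- switch(motif$where,
    "5p" = min(2L, n - w + 1L),
    "3p" = max(1L, n - w),
    "center" = max(1L, (n - w) %/% 2L + 1L),
    sample.int(n - w + 1L, 1L))
  substr(sequence, start, start + w - 1L) <- inst
  sequence
}

#' Simulate a labeled synthetic ncRNA dataset
#'
#' Draws \code{nPerClass} records per class label, split evenly over the
#' profiles carrying that label (the six-class default list holds two miRNA
#' profiles so that the class mixes mature- and precursor-length records
#' 50/50): lengths uniform within the profile range, background nucleotides
#' i.i.d. uniform over A/C/G/U, motifs instantiated by sampling their IUPAC
#' degeneracies, and templated stems copied as reverse complements with
#' per-base mismatches at the profile's rate.  Deterministic for a fixed
#' seed.
#'
#' @param profiles list of \linkS4class{ClassProfile} objects (see
#'   \code{\link{defaultProfiles}}).
#' @param nPerClass records per profile (>= 1).
#' @param seed RNG seed.
#' @return an \linkS4class{NcRNASet}; record ids encode profile and index.
#' @examples
#' simulateNcRNA(defaultProfiles(capLength = 500), 2, seed = 7)
#' @export
simulateNcRNA <- function(profiles, nPerClass, seed = 1L) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  prof_labels <- vapply(profiles, function(p) p@label, character(1))
  n_profiles_of_label <- table(prof_labels)
  n_per_profile <- integer(length(profiles))
  seen <- setNames(integer(length(n_profiles_of_label)),
                   names(n_profiles_of_label))
  for (p in seq_along(profiles)) {
    lab <- prof_labels[p]
    k <- n_profiles_of_label[[lab]]
    base <- nPerClass %/% k
    extra <- as.integer(seen[[lab]] < nPerClass %% k)
    n_per_profile[p] <- base + extra
    seen[[lab]] <- seen[[lab]] + 1L
  }
  ids <- seqs <- labs <- character(0)
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    tag <- gsub("[^A-Za-z0-9]+", ".", names(profiles)[p] %||% prof@label)
    for (i in seq_len(n_per_profile[p])) {
      len <- sample.int(prof@lengthRange[2L] - prof@lengthRange[1L] + 1L,
                        1L) + prof@lengthRange[1L] - 1L
      s <- switch(prof@structureTemplate,
        none = .rand_rna(len),
        hairpin = .template_hairpin(len, prof@stemMismatchRate),
        multi_stem = .template_multistem(len, prof@stemMismatchRate),
        stop("unknown structure template"))
      for (m in prof@motifs) s <- .place_motif(s, m)
      ids <- c(ids, sprintf("%s_%05d", tag, i))
      seqs <- c(seqs, s)
      labs <- c(labs, prof@label)
    }
  }
  NcRNASet(id = ids, sequence = seqs, label = labs)
}
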