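---
title: "Multi-encoding neural classification of ncRNA classes: methods"
author: "mncr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-encoding neural classification of ncRNA classes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Non-coding RNA (ncRNA) classes — lncRNA, miRNA, rRNA, snRNA, snoRNA and
tRNA — are heterogeneous in length (from ~20 nt mature miRNAs to rRNAs of
thousands of nucleotides), in conserved sequence motifs (snoRNA C/D boxes,
the snRNA Sm site, miRNA seeds) and in secondary-structure content
(pre-miRNA hairpins, the tRNA cloverleaf). `mncr` implements a
classification stack that feeds three complementary encodings of a
molecule into convolutional and dense neural networks and integrates the
sequence and graph channels late, at the penultimate layer.

# Encodings

**Ordinal sequence channel.** Sequences are uppercased and mapped through a
17-token vocabulary: the 16 IUPAC one-letter codes (both `T` and `U`, so
that DNA- and RNA-convention databases can be mixed without information
loss) plus the padding character `_` at code 0. Sequences are right-padded
to 12,000 positions by default. The code order `_ A C G T U R Y S W K M B D
H V N` is frozen for reproducibility; only the cardinality is fixed by the
design, so a frozen order is required for stable decoding.

**Combined nucleotide–substructure channel.** A dot-bracket structure is
annotated per position with one of six substructure states: `S` (paired,
stem), `H` (hairpin loop), `I` (internal loop or bulge: a loop closing
exactly one inner helix), `M` (multi-loop: two or more inner helices), `F`
(external, 5' of the first pair) and `T` (external, 3' of the last pair).
Two conventions had to be fixed where the six-state alphabet is silent:
external positions *between* two top-level helices are labeled `M`
(multi-loop is the closest semantic; the alphabet has no "external" state),
and a fully unpaired molecule is labeled all `F`. The annotation is
combined with the nucleotide into a 26-token vocabulary: 24 characters for
{A, C, G, U} x {F, T, S, M, H, I} in row-major order, anchored at
(A, F) = `Q`, plus `N` for any non-ACGU nucleotide regardless of structure,
plus `_`. The 24 characters run `Q..Z` then `a..n`; a straight ASCII run
from `Q` would collide with the padding character `_`, so the run skips the
punctuation block. `T` is a distinct token in the sequence channel but is
normalized to `U` here, which is what makes the combined alphabet close at
exactly 24 + 2 tokens.

**Hashed graph channel.** Secondary structure is predicted per window (150
nt, shifted by 25% = 37 nt, the final window anchored at `length - 150` so
every window is full-width) with up to 3 structure representatives
("shreps") per window. Each representative becomes a graph: vertices are
positions labeled `nucleotide + substructure state`, edges are the backbone
plus the base pairs. Neighborhood-subgraph pair features — canonical
strings of the radius-r neighborhoods (r ≤ 1) of two roots at graph
distance ≤ 4 — are hashed with a fixed, platform-independent FNV-1a hash
into 2^15 = 32,768 buckets, and counts are accumulated over all
representatives without per-window normalization (the accumulation
contract is deliberately simple and frozen). Before entering a dense
network the count vectors are row-L2-normalized (`normalizeRows()`), the
usual preprocessing for hashed graph-kernel features; the encoder output
itself stays raw counts.

# The folding engine

The built-in engine is a Nussinov-style base-pair maximization over nested
structures (Watson–Crick plus GU wobble; IUPAC ambiguity codes unpairable;
at least 3 unpaired positions in every hairpin loop), with a deterministic
traceback (leave the 5'-most position unpaired whenever that attains the
optimum, otherwise pair it with the smallest admissible partner). It
replaces a thermodynamic MFE folder deliberately: the downstream encoders
only require a valid, deterministic dot-bracket contract, and a
base-pair-maximal structure provides exactly that without a binary
dependency. An `external_mfe` engine delegates to an `RNAfold` binary when
one is on the PATH and falls back to the built-in engine otherwise.
Suboptimal representatives are generated by iteratively forbidding the
5'-most pair of the latest structure and refolding, keeping distinct
structures — a declared stand-in for the shape-representative semantics of
thermodynamic folders, with the same interface. Energy models and
pseudoknots are out of scope.

# Architectures

* **GrEnc** — dense ReLU layer of 10 nodes on the 32,768-dim graph vector,
  then a softmax output (6 or 10 classes): 327,756 trainable parameters at
  the 6-class default.
* **SeqEnc** — 4-dim embedding of the 17 tokens, four convolutional blocks
  (two length-preserving ReLU conv layers of 64 kernels each, then max
  pooling), kernel sizes 3/7/11/17 and pools 4/4/2/2, dropout 0.5,
  flatten, dense ReLU of 10, softmax. Pooling uses floor division with no
  partial windows, so 12,000 positions become 187 (12000 → 3000 → 750 →
  375 → 187).
* **StrEnc** — identical to SeqEnc but over the 26-token combined alphabet
  and with kernel size 7 in every block.
* **MncR** — the SeqEnc and GrEnc branches in parallel; their 10-node
  penultimate layers concatenate to a 20-node layer followed directly by
  the softmax output. Branch weights are freshly initialized, never copied
  from the solo models.

The engine realizing these specs is part of the package: embedding, 1-D
convolution (im2col to a single BLAS product per layer), max pooling with
first-match tie-breaking, inverted dropout (training only; inference is
deterministic), dense layers, softmax with categorical cross-entropy, and
Adam. Embedding row 0 (padding) is trainable like any other row — no
masking is applied. Embeddings initialize uniform in ±0.5 (a scale chosen
so the convolution stack receives usable signal from the first epochs at
the protocol learning rate); dense and convolutional weights use
Glorot-uniform. `countParameters()` on a spec walks the declared shapes;
on a realized model it counts the allocated arrays; the two must agree.

# Training protocol

Adam with learning rate 0.001, batch size 100, categorical cross-entropy
with optional per-class loss weights `w_c = N / (K n_c)` (inverse frequency
normalized to mean 1; all 1 on balanced data). After every epoch the
validation loss is computed (unweighted, dropout off). Every strict
improvement of the minimum validation loss checkpoints the weights; ties do
not count as improvement; training stops after 5 consecutive epochs without
a new minimum, or at `maxEpochs` (default 500 — a practical termination
bound; the protocol itself has none). The returned model is the
checkpointed best, not the last. Ten-fold cross-validation splits the data
into balanced folds (per-class counts differ by ≤ 1), uses each fold once
for validation, and reports the per-epoch median validation loss across
folds; folds that stopped early carry their last loss forward so the median
stays defined at every epoch.

# Dataset construction

Records live in an `NcRNASet` (id, uppercase IUPAC sequence, label,
optional subtype). The builder applies a length filter of 15–11,922 nt
(both boundaries inclusive, following the min/max wording of the source
protocol), a miRNA length split (≤ 30 nt mature, ≥ 40 nt precursor,
31–39 nt excluded — the gap between the two stated thresholds), and greedy
identity clustering in the CD-HIT style: longest-first visiting order with
lexicographic id tie-break, a shared 7-mer prefilter, identity defined as
matches over the shorter sequence via an overlap alignment, threshold 0.90.
Balanced splits draw a fixed test set per class and split the remaining
pool 90/10 into train/validation, with subtype-balanced selection (equal
draw per subtype, remainder distributed deterministically over subtype
order; partition membership within the selected pool is randomized under
the seed). Fine-grained relabeling expands the 6-class scheme to 10
classes: snoRNA by subtype (C/D-Box, H/ACA-Box, scaRNA), rRNA by subtype
(5S/5.8S short; 23S/25S/28S/SSU long), miRNA by length. Subtypes outside
these lists (e.g. mitochondrial rRNA) raise an error rather than being
silently binned.

# Benchmark harmonization

Comparing classifiers with different label schemes uses an explicit rule
object: fine-grained labels merge into their parent class, labels present
in only one scheme are dropped (`DROP`), sequences longer than 750 nt and
mature-length miRNAs are excluded, and records with > 90% identity to the
reference training set are removed. Predictions that map to `DROP` count
as incorrect; a subtype confused with a sibling subtype of the same parent
class counts as correct. Overall scores are macro-averaged (unweighted
over classes); on balanced test sets macro and micro averages nearly
coincide, and macro is the frozen choice for imbalanced benchmark subsets.
The F1 of a class with neither true nor predicted samples is excluded from
the macro mean rather than counted as zero. The multiclass Matthews
correlation coefficient is computed from the full confusion matrix with
the standard multi-category covariance generalization; on 2x2 matrices it
reduces exactly to the classical binary formula. The 0.005 threshold on
row-normalized confusion-matrix cells affects rendering only.

# Synthetic data: what it emulates and what it does not

`defaultProfiles()` encodes one generative profile per class (two for
miRNA, so the class mixes mature- and precursor-length records 50/50):

| profile | length (nt) | signal |
|---|---|---|
| mature miRNA | 20–24 | 5' seed motif `UGAGGUAG` |
| precursor miRNA | 60–120 | hairpin (mismatch rate 0.1) + seed motif |
| tRNA | 70–90 | four designed stems + T-loop motif `GUUCGAUU` |
| snoRNA | 70–250 | C box `RUGAUGA` (5') + D box `CUGA` (3') |
| snRNA | 100–300 | Sm site `AAUUUUUGG` (center) |
| lncRNA | 200–4000 | motif-free background |
| rRNA | 1400–3000 | three conserved 40-nt blocks at 5'/center/3' |

Backgrounds are i.i.d. uniform over A/C/G/U (GC skew is deliberately off so
the learning signal is attributable to motifs and structure); motifs are
instantiated by sampling their IUPAC degeneracies; hairpin arms are reverse
complements with per-base mismatches at the profile rate. For desk-scale
runs, `capLength` caps the long classes: lncRNA to (200, cap) and rRNA to
(0.8·cap, cap) — fragments of molecules an order of magnitude longer than
the cap accumulate near it, while lncRNA keeps its broad spread — paired
with `padTo = 500` in place of the production default 12,000 (padding
length is a constant multiplier on compute, not on logic). The generator
reproduces class-specific length ranges, motif content and stem-loop
structure; it does **not** reproduce covariance structure, phylogenetic
relatedness, GC heterogeneity or database label noise, so passing the
synthetic recovery runs demonstrates that the pipeline can extract and
integrate the encoded signals — not that real-data accuracies transfer.

# Desk-scale study conditions

The end-to-end checks (and `scripts/acceptance.R`) use problem sizes chosen
to exercise every component on one CPU: 6 classes × 300 records at
`capLength = 500`, an 60/20/20 train/validation/test split via balanced
folds, and a *reduced* SeqEnc — single-conv blocks with 16 kernels, kernel
sizes 11/7/7, pools 4/4/2 (post-pooling length 31) — trained with the full
protocol (the first-block kernel is widened from 3 to 11 so single motifs
are visible to single-conv blocks). The structure-dominated variant strips
the sequence motifs from the precursor-miRNA and tRNA profiles, keeping
their structure templates, and compares the merged model against the
graph-only model on the same split; late integration recovering the
structure signal that the sequence branch alone cannot see is the expected
qualitative ordering. Training runs are seeded and reproducible on a fixed
platform and thread configuration.

# Numerical choices and degenerate inputs

* Folding traceback ties resolve toward unpaired/smallest partner; the
  optimum pair count is unique even where the structure is not.
* Empty sequences: `foldMFE("")` is `""`; encoders return all-padding
  vectors; `windowedShreps("")` is an error (a window cannot be empty).
* Probability floors of 1e-12 guard the cross-entropy; softmax subtracts
  the row maximum before exponentiation.
* Max pooling drops a partial trailing window (floor division), matching
  the declared 12,000 → 187 arithmetic.
* Confusion-matrix degeneracies: precision/recall of an absent class is 0
  by convention inside per-class tables, absent classes are excluded from
  macro means, and an MCC with a zero denominator is 0.
* `makeFolds` requires at least one record per class per fold and is the
  single source of fold randomness (one seed, one assignment).

# Known limitations

The folding engine maximizes pair counts, not free energy, so its
structures differ from thermodynamic predictions in detail; the graph
features hash with unavoidable (deterministic) collisions at 15 bits; the
training engine is single-threaded R on BLAS and is sized for desk-scale
experiments, not for the full 60,005-sequence production runs; and the
synthetic generator's independence assumptions make its classes easier to
separate than real database classes at equal sample sizes.
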