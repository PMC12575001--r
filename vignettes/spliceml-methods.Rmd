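---
title: "spliceml: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceml: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science behind `spliceml`: the model and its
assumptions, the data conventions every stage shares, the tunable parameters
that matter, what the synthetic-genome generator does and does not emulate,
and the numerical design choices made where the design was genuinely open.

## The prediction problem

Splice-site prediction is framed as per-nucleotide 3-class classification:
every position of a pre-mRNA (sense-strand) sequence is scored as *none*,
*acceptor*, or *donor*. The input is the one-hot encoded sequence
(A = [1,0,0,0], C = [0,1,0,0], G = [0,0,1,0], T/U = [0,0,0,1]; N and any
IUPAC ambiguity code = [0,0,0,0]) and the model outputs a softmax
distribution over the three classes at each position. Labels come from
annotated intron boundaries; predictions are probabilities, so downstream
uses (site calling, variant delta scores, calibration) all operate on the
same scale.

## Splice-label convention

The package uses one label convention everywhere (labeling, BED output,
evaluation, ISM site selection): **the donor label sits on the last exonic
base upstream of an intron, and the acceptor label on the first exonic base
downstream of it**. The intron's boundary dinucleotides are therefore at
offsets +1/+2 from a donor label and −1/−2 from an acceptor label. Whether
the label belongs on the exonic or the intronic side of the junction is a
genuine convention choice; annotations encode exons, so labeling the
terminal exonic bases keeps label positions derivable from exon intervals
alone. The constant `SPLICE_LABEL_CONVENTION` marks every code path that
depends on it.

With `canonical_only = TRUE`, an intron contributes labels only when its
terminal dinucleotides are GT–AG or GC–AG (U2-type) or AT–AC (U12-type);
otherwise all annotated introns are labeled. The canonical transcript of a
gene is the one with the largest *spliced* (exonic) length — not genomic
span, since a transcript's information content is exonic — with ties broken
by the lexicographically smallest transcript ID so the choice is
deterministic.

## Dataset geometry

Gene sequences are segmented into `ceil(L / 5000)` core windows of 5,000 nt,
each extended by 5,000 nt of context per side (window width 15,000 nt).
Positions beyond the gene are N-padded in `X` and carry the all-zero padding
label in `Y`, so `Y` rows are one of [1,0,0] / [0,1,0] / [0,0,1] / [0,0,0].
A 22,000 nt gene therefore yields 5 segments with `X` of shape
(5, 15000, 4) and `Y` of shape (5, 5000, 3), the last core holding 2,000
real bases. At training time the stored 5,000 nt context is trimmed
symmetrically to the model's flanking size, so one dataset serves all four
architectures.

The on-disk container stacks genes into groups of 100 (X, Y, gene index)
and round-trips losslessly; it is implemented with native R serialization.

Chromosome splitting supports the fixed human partition (test chromosomes
1, 3, 5, 7, 9 — `chr`-prefixed or bare names) and a seeded random method
that shuffles chromosomes and accumulates them into the training set until
the cumulative length reaches the training fraction (default 0.8; `>=`
comparison at each step, ties resolved by shuffle order). Pseudogenes
(feature type or biotype `pseudogene`, `transcribed_pseudogene`,
`processed_pseudogene`) are removed. Paralogous test genes are removed by
aligning test against training sequences — minimap2 with the
high-divergence `asm20` preset by default, identity = matches / alignment
length, coverage = aligned query length / query length — dropping a test
gene only when an alignment *strictly exceeds both* the 0.8 identity and
0.8 coverage thresholds (coverage is measured on the test sequence, a
choice the interface documents). A built-in 15-mer Jaccard containment
fallback (≥ 0.8 treated as exceeding both thresholds) keeps the pipeline
functional without the external aligner. Only test genes are ever removed;
the training set is untouched.

## Model architecture

Each model is a dilated residual CNN parameterized by a kernel-size vector
`W` and a dilation vector `AR`, one entry per residual unit:

| flank | W | AR | units | skip merges |
|---|---|---|---|---|
| 80 | 11 ×4 | 1 ×4 | 4 | 1 |
| 400 | 11 ×8 | 1 ×4, 4 ×4 | 8 | 2 |
| 2000 | 11 ×8, 21 ×4 | 1 ×4, 4 ×4, 10 ×4 | 12 | 3 |
| 10000 | 11 ×8, 21 ×4, 41 ×4 | 1 ×4, 4 ×4, 10 ×4, 25 ×4 | 16 | 4 |

An initial 1×1 convolution projects the 4 input channels to the trunk width;
each residual unit applies (batch norm → leaky ReLU, slope 0.1 → dilated
convolution) twice and adds the result to its input; after every fourth unit
a 1×1 convolution merges the trunk into a skip accumulator; the accumulator
is cropped by `CL/2` per side and projected to 3 channels with a
per-position softmax. The cropping length `CL = 2 Σ AR·(W − 1)` equals the
flanking size in all four configurations, and — because each convolution
uses zero-padded "same" convolutions whose per-side receptive half-width
sums to exactly `CL/2` — the crop removes precisely the positions that edge
padding can influence. Two consequences the test suite exploits: output
length is always `input − flank` for any input length, and predicting a long
sequence whole or in overlapping windows (context `flank/2` per side) gives
identical probabilities.

Design points the architecture description leaves open, fixed here:

- **Trunk width**: 32 channels by default (configurable). Large enough to
  hold the handful of motif detectors the task needs, small enough to train
  on a CPU.
- **Order inside a unit**: pre-activation (norm → activation → convolution),
  the standard residual-network ordering that keeps the identity path clean.
- **Batch norm**: eps 1e-5, momentum 0.1 (framework-typical defaults,
  recorded in the configuration); running statistics are used in inference
  so prediction is deterministic.
- **Initialization**: Kaiming fan-in normals for convolutions (gain for
  slope-0.1 leaky ReLU), unit scale / zero shift for batch norm; seedable.

The entire network — forward and backward — is implemented in the package on
BLAS matrix products (`im2col` unfolding for the dilated convolutions), so
no external deep-learning framework is required. Gradients are verified
against central finite differences in the test suite.

## Training

Losses are masked per-position means over non-padding positions: categorical
cross-entropy, or focal loss `-(1 - p_t)^γ log p_t` (γ = 2 by default;
γ = 0 recovers cross-entropy exactly). Both losses are the standard
negative log-likelihood forms, non-negative and zero exactly when every
non-padding position is predicted one-hot correct. Padding rows carry no
loss. One numerical point deserves emphasis: the gradient with
respect to the logits is computed in the fused softmax-plus-loss form
(`p − y` for cross-entropy), *not* by chaining through the clamped
`log(max(p, eps))`. Chaining through the clamp silently zeroes the gradient
at any position whose true-class probability underflows the clamp — exactly
the rare splice-site positions a class-imbalanced run saturates first —
which freezes training in the trivial all-background solution.

Optimization is AdamW (decoupled weight decay, default 0.01; betas 0.9 /
0.999) at learning rate 1e-3 with either scheduler:

- **multistep** (default): 0.5 decay at every epoch from the sixth onward
  (the "decay from the sixth epoch" phrasing is ambiguous between a single
  and a repeated decay; repeated was chosen, matching the usual multistep
  semantics of a milestone list 6, 7, 8, ...);
- **cosine warm restarts**: `T_0 = 5`, `T_mult = 1`, `eta_min = 1e-5`.

The training windows are split 90:10 into training and validation with the
run seed; early stopping triggers after `patience = 2` epochs without a new
best validation loss, and the best-validation weights are returned. The
early-stop metric is validation loss (the patience value is specified, the
metric is not; loss is the quantity the optimizer sees). Divergence (a
non-finite loss) aborts with a diagnostic rather than returning garbage.

Transfer learning loads a checkpoint and trains only selected parameter
groups, ordered `conv_in, skip0, unit_1..n, skip_1..m, conv_out`;
`unfreeze = "all"` trains everything, `last_k` trains the trailing `k`
groups (`k = 0` is a strict no-op, returning the pretrained weights —
frozen units also keep their batch-norm running statistics fixed, otherwise
"frozen" weights would still drift through the normalization state).

## Calibration

Class-wise temperature scaling divides the logit of class `c` by `T_c`
before the softmax. `T` is fitted by minimizing the validation NLL with
Adam (lr 0.01), plateau-driven lr reduction (factor 0.1, patience 2), early
stopping at min-delta 1e-6 over 2 epochs, and `T` clamped to [0.05, 5];
initialization is T = 1, so the fit can only improve NLL. All non-padding
positions pool into the calibration set (no background down-sampling; an
optional cap guards memory). ECE uses 30 uniform bins on the
predicted-class confidence; reliability curves are one-vs-rest per class
with binomial normal-approximation CIs (`z = 1.96`). One caveat is
documented rather than hidden: *scalar* temperature scaling provably
preserves the per-sample argmax, but *class-wise* temperatures can in
principle change it; the ranking-invariance property is asserted in the
test suite for the scalar case only.

## Prediction and variant scoring

Prediction tiles a sequence with 5,000 nt cores, adds `flank/2` context per
side (N-padded at the ends), averages probabilities across all supplied
models (deep ensembling), and concatenates the cores, so every input base
is scored exactly once. Sequences longer than `split_threshold` (default
1,500,000) are processed in chunks overlapping by `flank/2`; chunking
affects memory only, never scores. Site calls above the threshold (default
0.5) are written as 0-based half-open single-base BED records with the
probability in the score column.

Variant delta scores compare acceptor/donor probability arrays over the
101 positions (distance 50) around a variant between the reference and
alternate alleles: `DS_AG = max(a_alt − a_ref)`, `DS_AL = max(a_ref −
a_alt)`, `DS_DG = max(d_alt − d_ref)`, `DS_DL = max(d_ref − d_alt)`, the
donor-loss channel mirroring the acceptor pair by symmetry.
Scores are clamped at 0 with delta position 0 when no positive difference
exists; delta positions break ties toward the smallest absolute offset,
then upstream. Alternate-allele arrays are aligned to reference coordinates
by skipping inserted positions and giving deleted reference positions the
score at the deletion junction. Flanking context is real genomic sequence
(N-fallback only at chromosome ends); scoring runs on the gene's sense
strand. Variants outside annotated genes, closer than `flank` to a
chromosome end, or deletions longer than `2 × distance` are skipped with a
reason code, and annotated VCFs preserve every input record.

## Evaluation and ISM

Top-k accuracy takes the `k · n_true` highest-scoring positions per class
and reports the fraction that are annotated sites; positions pool across
the evaluated gene set (per-gene averaging is available via the function's
inputs). Ties at the cutoff are included with the denominator unchanged; a
stable-truncation alternative sits behind the `ties` argument. Confusion
metrics use the standard definitions (the printed equation block in the
source description mixes up TP/FP/TN/FN between the three ratios; the
surrounding text names the standard metrics, which is what is implemented),
and AUPRC is step-wise average precision, which avoids the optimism of
trapezoidal interpolation.

ISM substitutes each base at each position of a window around a site,
re-scores the site, and reports importance
`S_ref − (S_A + S_C + S_G + S_T)/4`, where the reference base's
"substitution" scores `S_ref` itself; importance can be negative when
mutations strengthen the site. Batch motif matrices average raw score drops
across center-aligned sites. Ensemble-averaged scores are used throughout.

## The synthetic genome

The generator emulates just enough structure for every pipeline stage to be
verifiable against planted ground truth: multi-exon genes on both strands,
donor motifs `MAG | GTRAGT`, acceptors with a ≥10 nt polypyrimidine tract
and `YAG |` boundary, configurable GC–AG / AT–AC / non-canonical intron
fractions, near-consensus decoy motifs (Hamming distance 1) in introns for
cryptic-gain experiments, and uniform-background intergenic sequence.
Defaults describe the package's reference toy-genome conditions: 8
chromosomes × 250 kb (2 Mb), 80 genes, exons of 120–300 nt, introns of
150–450 nt, exact consensus motifs (degenerate only at the IUPAC M/R/Y positions; strength configurable), 5% GC–AG and 2% AT–AC introns. These
motif strengths are deliberately strong — the point is a task a small model
learns in minutes on a CPU, so that end-to-end tests exercise real learning
rather than mock scores.

What it does **not** emulate, and what passing tests therefore do not show:
degenerate real-world motif variability, branch points, exonic/intronic
splicing enhancers and silencers, alternative isoforms, overlapping genes,
repeats, or GC heterogeneity. Accuracy on the toy genome says the
implementation is correct, not that a model trained on it transfers to real
genomes.

All randomness derives from the `synthetic_spec` seed; identical specs produce
byte-identical FASTA/GFF output.

## Problem sizes in the test suite

The automated tests run the full pipeline at deliberately small scales
chosen as the package's own reference conditions: the end-to-end check
generates the default 2 Mb / 80-gene genome, trains two independently
seeded flank-80 models (32 channels, cosine-warm-restart schedule, up to
10 epochs each), and evaluates their ensemble on held-out genes;
chunk-equivalence and calibration-recovery checks use 1–30 kb sequences and
10,000 pooled positions. The CLI, IO, and metric tests use kilobase-scale
fixtures built in code.

## Known limitations

- Training is CPU-bound R; it is sized for toy genomes and method
  validation, not genome-scale training runs.
- GTF support covers the common `gene_id`/`transcript_id` attribute layout;
  exotic dialects may need pre-conversion.
- The dataset container is R-native serialization, readable by this package
  rather than by generic HDF5 tooling.
- Class-wise temperatures can in principle perturb argmax-based metrics
  (see Calibration above).
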