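---
title: "FPsieve: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FPsieve: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FPsieve)
```

## The statistical problem

A single-sample GATK call set contains mostly true variants and a minority
of false positives (FPs) concentrated in difficult genomic contexts. Two
properties shape the learning problem. First, the classes are imbalanced
(roughly a quarter of labeled training calls are FPs when FPs are
oversampled across capture kits), and the cost structure is asymmetric: in
clinical use, filtering out a true variant (a missed diagnosis) is far
worse than letting an FP through (an extra confirmation). Second, pooling
calls from several capture kits creates *duplicate* observations of the
same variant with different quality metrics; any split that separates
duplicates leaks information between train and test.

FPsieve therefore trains a cost-sensitive classifier under duplicate-aware
resampling, selects hyperparameters under explicit sensitivity
constraints, and reports a probability — not a verdict — for each call.

## Features

Each call is described by 20 features (`fpFeatureNames()`):

| group | features | missing-value rule |
|---|---|---|
| GATK metrics | `dp, qd, fs, sor, mq, gq` | required; absence is an input error |
| rank sums | `mq_rank_sum, base_q_rank_sum, read_pos_rank_sum` | absent for homozygotes; filled with −999, recorded by `is_homo` |
| window context | `gc, cpg` (±75 bp) | defaults 0.42 / 0.02 when the track or contig is unavailable |
| variation type | `is_tv` | 0.5 inside variation-type track gaps |
| conservation | `anc_frequency, is_derived` | ancestral base `O` when unknown; `is_derived` then 0.5 |
| alleles | `ref_frequency, alt_frequency` | frequency-encoded; unseen category → 0 |
| consequence | `transition_amino_acid, family_transition, family_pair` | `family_pair` 0 and configured constants when amino acids unknown |

Three conventions deserve a note because the feature names alone do not fix
them:

* **`is_tv` polarity.** 1 encodes a transversion, matching the name (is
  the variation a transversion?). The 12 ordered base pairs are covered
  exhaustively by tests.
* **`is_derived` comparand.** The *alternative* allele is compared with the
  ancestral base: 1 when they differ. Comparing the genotype-carried
  alleles instead would entangle the feature with zygosity, which
  `is_homo` already captures.
* **Missing booleans encode as 0.5** — "the condition holds with
  probability one half" — so a tree can still split missingness from both
  certain states.

Chromosome and position are identifiers only; they are carried next to the
feature matrix but never inside it.

### Amino-acid matrices

The amino-acid transition and radical-group family matrices are
configuration, not estimates from data: the shipped defaults
(`defaultAminoAcidMatrices()`, serialized in
`inst/extdata/aa_matrices.json`) are **synthetic**, computed from
single-nucleotide codon accessibility of the standard genetic code —
`P(i → j)` proportional to the number of codon pairs encoding `i` and `j`
that differ by one base, stops excluded, rows normalized. This captures
the genuine structure that some substitutions are reachable by one
nucleotide change and others are not, while remaining fully reproducible
offline. Any empirically fitted matrix can be swapped in via
`loadAminoAcidMatrices()`; lookups are validated at load time, never per
variant. Transitions involving the unknown code `U` take a configurable
constant (default 0).

### Encoding and leakage

Frequency encodings are relative category frequencies of the *training*
rows. During cross-validation they are refitted inside every fold from
that fold's training portion; for the final model they are fitted on the
full training partition (before undersampling, since the encoding is a
property of the training data distribution, not of the balanced subsample)
and frozen in the bundle. Prediction never re-fits an encoding. Unseen
categories at prediction time encode to 0 (configurable), the conservative
choice: an allele never seen in training provides no evidence of being
common.

## Splitting, imbalance and costs

`stratifiedGroupSplit()` and `stratifiedGroupKFold()` operate on variant
groups (`chrom:pos:ref:alt`), assigning whole groups greedily per class so
that row-level class proportions track the full dataset (within ±2
percentage points under realistic group structures — the quantification we
attach to "the distribution is preserved", since finite groups make exact
preservation impossible). `covariateShiftCheck()` then fits a 5-fold
cross-validated logistic discriminator between the partitions; its PASS
threshold is AUC ≤ 0.55 rather than the idealized 0.50, because the
out-of-fold AUC of a null discriminator is itself a random variable with
spread of a few hundredths at these sample sizes.

Each CV training fold is balanced by undersampling true variants 1:1 to
the FPs (FP rows are never discarded — they are the scarce class).
Misclassification costs enter every fit as per-class observation weights:
`c1` on FPs, `c2` on true variants. For the random forest this weights the
bootstrap sampling (`ranger` case weights), for the decision tree and
logistic regression the loss directly. The default `costMatrix(1, 4)`
protects true variants; the exact ratio is a tunable with the usual
trade-off — raising `c2/c1` buys sensitivity with FP recall.

Model selection is constrained: among candidates with mean CV TPR > 0.99
and TNR > 0.40 (strict inequalities), maximize AUC-ROC; if the constraint
set is empty, fall back to the highest TPR, ties broken by TNR, then by
candidate order (the last tie-break is an arbitrary but deterministic
artifact rule).

## Interpretation

`permutationImportance()` measures the mean drop in AUC-ROC (the selection
objective; the metric is configurable) over seeded within-dataset
shuffles of one feature at a time. Shuffles are applied to the *raw*
underlying column — e.g. the Ref base behind `ref_frequency` — so the
three encoded categoricals are permuted coherently for every algorithm.

`explainVariant()` returns interventional Shapley values: contributions
are averaged over feature-insertion paths (background row → explained
row) across permutations of the feature order, with the expectation taken
over a background sample. When `factorial(p)` is small (≤ 720 by
default) all orders are enumerated and the attribution is exact; otherwise
orders are sampled. Additivity — base value plus contributions equals the
model's score — holds *by construction* for any number of sampled orders,
because every path telescopes; sampling only affects the variance of
individual attributions. This uniform construction was chosen over
tree-specific path attribution so that random forest, decision tree and
logistic bundles are explained identically.

The compact model retains features with importance **≥ the median** (so
all-equal importances retain everything; with 20 features and strictly
positive spread this keeps 10–11, depending on ties around the median) and
re-runs the full grid search and constrained selection on the reduced
feature set.

## The synthetic call-set generator

`generateCallset()` emulates the statistical structure the pipeline must
face, as a pure function of `(config, seed)`:

* class imbalance (default 27% FPs);
* class-conditional truncated-normal metric distributions — FPs centered
  at lower QD/MQ/DP/GQ, higher FS/SOR, shifted rank sums, the direction
  hard filtering exploits. The default separation is calibrated to a
  moderately separable problem (a traditionally trained forest reaches a
  CV AUC near 0.99 at a few thousand variants), deliberately easier than
  real exome data but hard enough that the cost-sensitive/traditional
  trade-off and the feature ranking are non-trivial;
* structural missingness: homozygous calls (30%) lack all three rank
  sums; ancestral-base and variation-type information are missing with
  class-conditional rates calibrated so that, at the default class ratio,
  ~91% of variation-type-missing and ~79% of ancestral-missing calls are
  FPs (the overall ancestral-missing rate is set to 5%);
* transition/transversion composition differing by class (70% vs 45%
  transitions);
* duplicate calls: 10% of variants are re-emitted by up to two additional
  kits with jittered metrics (`KIT` INFO tag), exercising the
  duplicate-aware splitting;
* a coding fraction (30%) with amino-acid consequences drawn from a codon
  model consistent with each ref/alt pair.

Scenario presets pin the study conditions: `imbalanced-27` (the
defaults), `separable` (large shifts; the selection constraints must be
satisfiable), `hard` (overlapping distributions; the cost-sensitivity
direction is visible), and `shifted-test` (an additive covariate shift
applied to the test partition, which the shift check must flag).

**What passing tests do and do not show.** The generator produces
conditionally independent metrics given the class label; real call sets
have correlated metrics (QD and DP share a numerator), spatial batch
structure, reference bias and haplotype-dependent labeling error, none of
which are modeled. Green tests therefore validate the *machinery* —
encodings, splits, selection, calibration, explanations — under known
ground truth, not the accuracy the filter would reach on real exomes.

## Numerical choices and degenerate inputs

* AUC-ROC is the Mann–Whitney rank statistic with ties averaged;
  single-class inputs yield `NA` rather than a fabricated value.
* MCC uses the closed form with the denominator factored as a product of
  square roots to avoid integer overflow on large confusion counts.
* The classification rule is `score >= threshold` for "true variant";
  `writeScoredVcf()` marks `FP_ML` only when a score is *strictly below*
  the threshold, so a score equal to the threshold passes.
* The sensitivity tuner returns the largest threshold achieving the
  target TPR; monotonicity makes that threshold also TNR-optimal among
  achieving ones. A target above 1 falls back to the minimum score with a
  warning flag.
* Window features truncate at contig edges and use the available
  (non-N) bases as denominator; fully uninformative windows fall back to
  the genome-wide defaults.
* `readSNVs()` splits multiallelic sites into per-ALT records (the
  feature space is per-allele; the alternative — dropping such sites —
  discards signal) and skips indels/MNPs with a count.
* Truth-set matching is exact by `(chrom, pos, ref, alt)`. On real data a
  haplotype-aware comparator can label differently around complex
  regions; exact matching was chosen for determinism and is a known
  deviation risk outside synthetic data.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
unit tests use 150–4,000 variants, calibration-style properties use
20,000–50,000, and the acceptance script trains on a 10,000-variant call
set with 10-fold CV. These sizes were chosen so the full battery of
seeded replicates (hundreds of splits, 100 importance runs, 20
cost-sensitivity replicates) completes quickly on a laptop while keeping
binomial noise well inside the asserted tolerances.

## Known limitations

* No indel model; the feature space and the SNV filter are substitution-
  specific by design.
* The amino-acid matrices are a structural stand-in, not empirical
  substitution probabilities.
* Oversampling FPs from sibling sequencing runs is represented inside the
  generator (duplicates with jitter), not as a standalone data operation.
* `oAA`/`nAA` come from a user-supplied consequence table; the package
  does not run a consequence annotator.
* Per-variant explanations cover additive attributions only — no
  interaction values.
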