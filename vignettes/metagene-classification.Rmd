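---
title: "Metagene classification by ROC feature ranking: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagene classification by ROC feature ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaroc)
```

## The model

`metaroc` classifies samples into two phenotype classes (coded 0/1) from a
log-scale genes × samples expression matrix. The classifier is a single
univariate score per sample, the *metagene*:

1. **Feature scoring.** Each gene receives an AUC against the phenotype,
   computed through the Mann–Whitney identity with midranks; ties between a
   positive and a negative sample contribute 1/2 of a concordant pair, so
   the value equals the trapezoidal area under the empirical ROC curve.
2. **Orientation.** Genes with AUC < 0.5 are negatively associated with
   class 1; their expression is negated, mapping AUC to 1 − AUC. The
   performance of a gene is thus the oriented AUC max(AUC, 1 − AUC), with a
   recorded sign.
3. **Averaging.** The top `xgenes` genes by oriented AUC are averaged
   (after sign correction) into the metagene. Averaging exploits the
   co-regulation of disease-associated genes and damps single-gene noise —
   this is why a 50–200-gene metagene typically beats its best individual
   member.
4. **Thresholding.** Samples are sorted by metagene value and every
   achievable split is scored by plain (unbalanced) training accuracy. The
   decision threshold is the midpoint between the two border samples of the
   best split; prediction is class 1 iff metagene > threshold, with
   equality deliberately falling to class 0.

The model object holds only the ordered gene ids, their signs, the
threshold, and training metadata. There are no per-gene weights, which is
exactly what makes the signature portable.

Assumptions worth stating: expression is on a log-like scale so that an
arithmetic mean is meaningful; per-gene distributions are roughly unimodal
within a class (the AUC itself is rank-based and needs no distributional
assumption, but the *averaging* step benefits from comparable scales, which
is why the preprocessing helpers centre genes and optionally
quantile-normalize samples); and the two classes are both represented in
every training set.

## Evaluation protocol

Accuracy is reported as **balanced accuracy** (sensitivity + specificity)/2,
which is invariant to class prevalence; the plain accuracy is used only
inside threshold fitting. `loocv()` repeats the *entire* pipeline — ranking,
signature selection, sign assignment, threshold fit — on the n − 1 retained
samples of every fold, classifies the held-out sample, and pools all
held-out calls into one confusion table per signature size. Pooling (rather
than averaging per-fold accuracies) treats the cross-validation loop as an
estimator of whole-dataset performance; with leave-one-out folds a per-fold
accuracy would be a meaningless 0/1 anyway.

Feature selection inside the fold is the critical detail. Selecting genes
on all samples first and cross-validating only the threshold inflates null
data from chance (≈0.5) to well above 0.6 balanced accuracy; the test suite
constructs exactly this leaky variant as a positive control and asserts the
gap.

`external_validate()` implements gene-identity-only transfer: the validation
cohort re-derives per-gene signs and the threshold inside its own LOOCV
folds. Re-learning the signs per fold is a deliberate reading of the
protocol — signs are part of the AUC information that is *not* carried over,
and re-estimating them in-fold keeps the validation estimate leakage-free.
A per-gene additive batch shift is absorbed automatically: it moves the
metagene of every validation sample by the same constant, which the re-fit
threshold removes, and sign re-learning repairs any orientation flips.

## Null diagnostics

`randomize_dataset()` replaces each gene with Gaussian draws matching that
gene's own mean and SD. Per-gene (rather than whole-matrix) moments are
used so the randomized data preserve the marginal structure that the
observed AUC distribution is compared against; a `per_gene = FALSE` switch
gives the global alternative. `null_auc_interval()` then computes the
central interval of the per-gene null AUCs: with 10,000 genes and a
balanced 56-sample design the 99% envelope is ≈ [0.30, 0.70], matching the
normal approximation 0.5 ± z₀.₉₉₅·√((n₀+n₁+1)/(12 n₀ n₁)). The fraction of
observed genes outside the envelope, minus the (1 − coverage) expected by
chance, bounds the number of genuinely informative genes and hence the
useful signature size. Quantiles are the interpolated inverse-ECDF kind
(R's default type 7); the convention is stated because quantile definitions
differ across software.

## The synthetic-data generator

`synth_spec()` fixes the study conditions used throughout the tests: 2000
genes, 30 + 30 samples, 50 informative genes shifted by 1.5 within-class
SDs in class 1, half of them downward, unit within-class SD. These sizes
mirror a typical single-cohort two-class expression study: cohorts of 56–90
patients and signatures around 50 genes are the regime the method targets.
Noise is Gaussian per gene, a reasonable stand-in for log-scale array
intensities after centring. Optional equicorrelation within the informative
block is induced by a single latent factor per sample with loadings
dir·√ρ — the simplest structure under which averaging correlated,
co-regulated genes behaves like real signatures. `simulate_train_validation()`
draws two cohorts from one generative law and adds per-gene N(0, batch²)
offsets to the validation draw to emulate cross-platform shift.

What the generator does **not** emulate: heavy-tailed or count-based noise,
probe-level artefacts, correlated null genes, confounded batch structure,
and missing values. Passing tests on this generator therefore demonstrate
the correctness of the algorithms and the integrity of the protocol, not
clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* **Tie handling in AUC**: midranks, the convention that preserves the
  pair-counting interpretation exactly.
* **AUC exactly 0.5**: sign +1 (no flip); oriented 0.5 ranks last.
  Arbitrary but deterministic.
* **Equal oriented AUCs**: ranking ties break by gene id in C-locale order,
  so results are independent of input row order. (Implementations that
  inherit input order are not reproducible under row permutation; we prefer
  reproducibility and document the divergence.)
* **Threshold ties**: among splits of maximal accuracy, the one with the
  highest sensitivity wins, then the largest threshold. When the best split
  leaves all samples on one side, the threshold is offset beyond the
  extreme value by half the smallest positive gap (1 if all values are
  equal) so it stays finite and serializable; with all metagene values
  equal and classes balanced this yields "call everything positive" at
  value − gap.
* **Imputation distance**: mean squared difference over mutually observed
  samples, so genes with different missingness are comparable; neighbour
  ties break by row order, and imputation uses only originally observed
  values (no chaining).
* **Preprocessing order**: duplicate-gene merging precedes imputation-based
  analyses, so neighbour search operates on unique genes.
* **Quantile-normalization ties**: tied entries receive the mean of the
  reference values at their tied ranks (limma's `ties = TRUE` behaviour).
* **Shapiro–Wilk** is capped at 5000 values per gene (an evenly spaced
  subsample beyond that), the standard implementation limit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the reference conditions above: 1000 random instances (n ≤ 30) for the AUC
oracle, 500 instances (n ≤ 50) for threshold optimality, 10,000 genes × 56
samples for the null envelope, 100 replicates of 200 genes × 40 samples for
the leakage guard, 10 seeds of the 2000-gene design for signal recovery and
for the signature-size sweep (5–300 in steps of 5, correlation 0.3). These
sizes keep every property in its asymptotic regime while the whole suite
runs in minutes on one core.

## Known limitations

The classifier is intentionally univariate after averaging: it cannot
represent interactions between genes or non-monotone relations between the
metagene and the class. Threshold fitting optimizes unbalanced accuracy, so
under severe class imbalance the fitted cut can favour the majority class
even though evaluation reports balanced accuracy. Gene-transfer validation
assumes the validation cohort is large enough to re-learn signs and
threshold (each class ≥ 2, realistically dozens); with very few overlapping
genes the re-learned signs become noisy. And the generator's Gaussian,
independent-null world is a lower bound on the difficulty of real data.
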