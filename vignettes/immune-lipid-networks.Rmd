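---
title: "Immune–lipid association networks: model, assumptions and design"
author: "lipidnrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune–lipid association networks: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnrr)
```

## The analysis in one paragraph

`lipidnrr` analyses a matched patient–control cohort in which each sample
carries two kinds of features: lipid species quantified by lipidomics and
inflammatory mediators (circulating cytokines/chemokines measured in
plasma, and inflammasome-related transcripts measured by qPCR). The goal is
a conservative map of which *disease-associated changes* in lipids move
together with *disease-associated changes* in immune mediators. The unit of
analysis is therefore not the raw measurement but the matched-pair fold
change, and the association filter is not a p-value on the marginal
correlation but the **non-rejection rate (NRR)** of a battery of q-order
partial-correlation tests, which asks whether an association survives
conditioning on other features.

## Preprocessing and the fold-change matrix

Raw tables are samples × features, non-negative, with missing cells where a
compound fell below the detection limit. Four steps run in a fixed order:

1. `clean_nonpositive()` — missing or negative cells become exactly 0.
2. `impute_half_minimum()` — per feature, zeros are replaced by half the
   smallest strictly positive observed value. After step 1 every
   problematic cell is 0, so "minimum" can only sensibly mean *minimum
   positive* value; with any other reading the imputed value would be 0 and
   the step a no-op. Features that are zero everywhere carry no signal and
   are dropped (with a logged warning) rather than erroring, the usual
   behaviour of exploratory omics pipelines.
3. log2 transform.
4. Autoscaling: each feature is centred and scaled to unit variance across
   **all** samples jointly — patients and controls together, before
   pairing — so the later subtraction operates on a common scale.

**SD convention.** Autoscaling divides by the sample standard deviation
(n − 1 denominator, as `scale()` does). The choice between the sample and
population convention rescales every column by the same constant
√((n−1)/n), so it cannot change any correlation, NRR, network or candidate
downstream; it only changes the numeric scale of the fold-change matrix.
We default to the sample convention because it reproduces the package's
worked example `(4, 2, 8) → (0, −1, 1)` in round numbers and matches base
R; `log2_autoscale(sd_method = "population")` switches, and the pipeline
manifest records the convention used.

The **fold-change matrix** has one row per pair: scaled patient value minus
scaled matched-control value. Pairing cancels every latent factor shared
within a pair (the age/sex matching variables, in the generator an explicit
pair-level random effect), which is why downstream inference is run on this
matrix and not on the raw samples.

## Spearman correlations and the non-rejection rate

Edge *weights* are pairwise Spearman correlations of the fold-change
matrix — rank-based, hence robust to the heavy tails that concentration
data keep even after log transformation. Edge *retention*, however, is
decided by the NRR, computed from Pearson-type covariance of the same
matrix: the conditional-independence test battery inverts covariance
submatrices, and the fold-change values are already continuous scores
rather than ranks. This split — a robust reported coefficient, a
covariance-based filter — mirrors how the two statistics are used in
practice.

For features *i*, *j* and a conditioning set *Q* of size *q*, the sample
partial correlation comes from inverting the covariance submatrix on
{i, j} ∪ Q (`r = −Ω_ij / √(Ω_ii Ω_jj)`), and `H0: r = 0` is tested with the
Fisher z statistic `z = √(n − q − 3)·atanh(r)` against the two-sided normal
critical value. The NRR of the pair is the fraction of non-rejections over
`n_tests` random draws of *Q*. Under a direct dependence the partial
correlation stays away from zero for every *Q*, so NRR → 0 as *n* grows;
under the global null the NRR concentrates near 1 − α; an association that
is merely induced by a shared neighbour collapses whenever that neighbour
enters *Q*, producing intermediate NRRs.

Defaults, all exposed in `nrr_config()` and echoed into the run manifest:

* `alpha = 0.05` — the conventional test level; the null-calibration test
  verifies the mean NRR lands in [0.93, 0.97] against the 0.95 target.
* `n_tests = 100` per pair — Monte-Carlo noise of a proportion at
  n = 100 is at most 0.05 SD, small against the 0.1 retention threshold.
* `q_policy = "uniform"` over `1..q_max` with
  `q_max = min(p − 2, n − 4, 20)` — the upper bound keeps the Fisher-z
  degrees of freedom `n − q − 3` positive at small cohort sizes (39 pairs
  forces q ≤ 35; the cap of 20 bounds cost at large p).
* `mode = "exhaustive"` enumerates *all* conditioning subsets of each
  configured order instead of sampling; it is the brute-force reference the
  Monte-Carlo path is tested against, and the Monte-Carlo path itself
  enumerates whenever a fixed-q request already covers every subset.

**Determinism.** Each pair's tests run on an independent substream of a
counter-based RNG keyed by (master seed, sorted pair indices), so the NRR
matrix is reproducible bit for bit and independent of evaluation order or
parallel scheduling. The inner loop is RcppArmadillo.

**Degenerate inputs.** A perfectly collinear pair makes every covariance
submatrix singular; its partial correlation is ±1 and every test counts as
a rejection (NRR = 0). A singular submatrix for any other reason — e.g. a
duplicated conditioning feature — is an error naming the offending set.
Constant columns get Spearman correlations of 0 with a warning.

## Thresholds, pruning and candidates

The NRR retention threshold (default 0.1, **inclusive**) is a required
configuration value: the package emits the NRR histogram
(`nrr_histogram()`) so the analyst can judge where the spurious bulk sits,
and performs no automatic threshold selection. Lipid–lipid edges are then
pruned: the network is read mediator-centrically, and lipid co-regulation
— real but overwhelming in edge count — is out of scope. Mediator–mediator
edges are kept (the inflammasome core is itself a finding), but the default
candidate report (`strong_candidates()`, |ρ| ≥ 0.5 inclusive) lists only
mediator–lipid pairs, with a flag to include mediator–mediator pairs.
Raising the NRR threshold or lowering the ρ threshold never removes a
previously retained candidate (monotonicity, property-tested).

## Group tests and the confounder scan

Per-feature patient-vs-control comparisons use one-way ANOVA with Tukey's
HSD. For two groups the studentized range satisfies q = √2·|t|, so the
Tukey p equals the pooled two-sample t-test p; the implementation uses this
identity directly at k = 2 (it is exact, whereas the numeric studentized-
range integral is only accurate to ~1e-7) and `stats::TukeyHSD` for k ≥ 3.
Tests default to the log2 scale, where the lognormal measurement noise is
closest to Gaussian and variance is stabilized; the p-value is invariant to
the subsequent autoscaling, so nothing depends on the SD convention above.

The medication scan fits, per feature, an ordinary Gaussian identity-link
linear model of the processed value on the antipsychotic flag, within the
patient stratum — controls are unmedicated by design, and including them
would make the flag partially encode case status. For a binary predictor
the coefficient and p-value coincide with the pooled t-test, which the
tests assert. Benjamini–Hochberg and Bonferroni adjustments are always
reported side by side.

## The synthetic cohort: what it emulates and what it does not

`make_ground_truth()` builds a catalog (default 185 lipids across TG, PC,
LPC, PE, PI, Cer, SM, ChoE; 11 plasma and 9 gene mediators) and a sparse
precision matrix over the features:

* an "inflammasome core": all pairwise edges among 6 gene mediators with
  positive partial correlation 0.9/(core_size − 1) = 0.18 — just inside
  the positive-definiteness bound 1/(core_size − 1), which makes the
  implied *marginal* core correlations ≈ 0.6, a tightly interconnected
  positive block;
* mediator–lipid cross edges (default 7) with target partial-correlation
  magnitudes drawn from [0.6, 0.75], negative with probability 0.73,
  assigned round-robin over the non-core (plasma) mediators. Spreading the
  edges keeps each planted pair nearly isolated in the graph, so its
  marginal correlation essentially equals the planted partial correlation —
  which is what makes recall measurable against a |ρ| ≥ 0.5 candidate
  threshold.

Positive-definiteness is enforced by shrinking all off-diagonals 5% per
round (at most 60 rounds, then an error); the final matrix is rescaled to
unit implied covariance diagonal and the *achieved* partial correlations
are recorded per edge. `simulate_cohort()` then draws, per pair, a shared
latent shift (SD 0.5 feature-SD units, modelling the matching) plus
individual multivariate-normal draws, adds group effects to patients
(default +1, +1, −1 SD on TG(50:1), TG(16:0/18:0/18:1) and PC(O-34:3) —
two triacylglycerols up, one ether phosphatidylcholine down; the magnitudes
are free parameters), exponentiates base 2 onto a lognormal concentration
scale around a baseline log2 abundance of 10, and censors each feature
below its 5% quantile to missing. The lognormal construction means the
pipeline's log2 step exactly recovers the latent Gaussian, so the planted
precision matrix remains the ground truth *after* preprocessing.

The generator does **not** simulate MS peak-picking artefacts, RSD
structure, batch or injection-order effects, non-lognormal heavy tails, or
lipid-class co-regulation blocks. Passing tests therefore demonstrate that
the statistical machinery recovers known structure under the stated
sampling model — not that any particular real cohort satisfies that model.

## Problem sizes used by the tests

The test suite validates exhaustive-vs-brute-force NRR agreement at
p = 8 / n = 40 (all 28 pairs, orders 1–2), null calibration on 8 datasets
of n = 60 / p = 12 (528 pairs), planted-structure recovery on ten cohorts
of 39 pairs with 100 lipids + 20 mediators and 10 planted cross edges
(recall ≥ 70%, false-discovery proportion ≤ 30%), and byte-identical
reproducibility of two full-scale pipeline runs (185 lipids + 20
mediators). These sizes exercise the full default configuration while
keeping the suite to about a minute.

## Known limitations

* The NRR battery tests *linear* conditional independence on the
  fold-change scale; purely monotone-nonlinear dependencies are seen only
  through their linear component (the reported weights are Spearman, but
  the filter is covariance-based).
* With 39 pairs, conditioning orders near `q_max` leave few degrees of
  freedom; the Fisher-z normal approximation is standard here but slightly
  liberal at `n − q − 3 < 20`.
* Half-minimum imputation underestimates the variance of heavily censored
  features; features censored beyond ~20% should be interpreted with care
  (the generator's default 5% censoring is representative of routine
  panels).
* The confounder scan is a per-feature marginal screen, not a joint
  adjustment; it flags medication associations but does not remove them.
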