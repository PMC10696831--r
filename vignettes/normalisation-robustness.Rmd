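---
title: "Normalisation robustness for methylation-array EpiScores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalisation robustness for methylation-array EpiScores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinorm)
```

## The problem

Epigenetic scores (EpiScores) are sparse weighted sums of CpG methylation
values trained to predict a trait. In practice a score is trained on one
cohort and projected onto another, and the projection sits downstream of a
normalisation step that may use information *across* samples. When a new
cohort is normalised on its own, its normalised values — and therefore every
individual's EpiScore — can differ from what they would have been had the
cohort been normalised jointly with a reference dataset. `epinorm` measures
that discrepancy. For each normalisation strategy it computes paired scores
(`score_separate`, `score_joint`) per individual and summarises them with
the median absolute difference (MAD), correlations with the phenotype,
incremental R², and percentile shifts.

A structural dichotomy organises the results. *Within-array* methods (raw,
SWAN, BMIQ, PBC, Noob) use only a single sample's values, so the two arms
are identical by construction; the package treats this as a theorem and
tests it to numerical exactness, not approximately. *Between-array* methods
(quantile normalisation across samples, functional normalisation, subset
quantile normalisation) couple each sample to the cohort composition and
can move individual scores when the reference changes.

## The synthetic two-cohort generator

Real methylation cohorts of this kind are access-controlled, so the package
ships a generator that emulates the features of two age-matched cohorts
processed in different batches. Biology is shared; technical parameters
differ by batch.

**Biological layer** (`simulate_true_betas()`): per probe class,

* *plain* CpGs: per-probe bimodal hypo/hyper means (Beta(2,8) / Beta(8,2))
  shared across samples, plus inter-individual variation `bio_sd` (default
  0.08 on the beta scale — the scale of variation seen at variably
  methylated CpGs, which is where trait signal lives);
* *imprinted-DMR* probes: centred at beta 0.5 (probe-level SD 0.02,
  sample-level SD 0.02) — their dispersion after normalisation is the DMRSE
  metric's target;
* *SNP-affected* probes: genotypes drawn under Hardy–Weinberg equilibrium
  at `snp_maf` (default 0.3), beta centred at {0.05, 0.5, 0.95} — the GCOSE
  metric's target;
* *X-linked* probes: female mean shifted above the male mean by
  `x_sex_margin` (default 0.30, male mean 0.20) — the Seabird metric's
  target.

**Technical layer** (`render_intensities()`): per probe and sample a total
intensity is drawn log-normally (mean 5,000 units, `sdlog` 0.15 — roughly a
15% chip-level intensity CV); methylated signal is `T·beta`, unmethylated
`T·(1−beta)`; each signal receives the batch's additive background (separate
Type I and Type II offsets, e.g. 600/250 vs 900/400 units) and the
multiplicative dye gain of its colour channel (e.g. Grn/Red 1.0/1.0 vs
1.25/0.85), plus Gaussian read noise (SD 50), floored at zero. Type II
methylated signal reads in the green channel and unmethylated in red; both
signals of a Type I probe share its declared channel, and its out-of-band
readings are background draws from the opposite channel. Bead counts are a
shifted Poisson; detection p-values are simulated directly (near zero, with
a configurable failure rate) rather than derived from a background model,
which keeps the QC filters testable without committing to any particular
detection-p construction.

This additive-background + multiplicative-dye + Gaussian-noise model is the
simplest one in which the three letters of the combinatorial method
nomenclature (background adjustment, between-array grouping, dye-bias
correction) each have a real consequence. What it deliberately omits:
chip-position spatial effects, probe cross-hybridisation, copy-number
artefacts, cell-composition differences, and any correlation structure
between neighbouring CpGs. Tests passing on this generator therefore
demonstrate the *mechanisms* (sample-wise invariance, dye-bias sensitivity,
metric behaviour), not performance on real arrays.

Causal CpGs for the phenotype are sampled from plain probes with mean beta
in (0.2, 0.8). CpGs near the fully methylated or unmethylated boundary have
essentially no room for inter-individual variation — in the generator their
variation is an artefact of truncation — and trait-associated variable CpGs
in practice sit in this intermediate range. Weights are
`Normal(0, effect_sd²)` (default 0.05) on the true M-values; log BMI adds
age, sex and ancestry-covariate effects plus `Normal(0, 0.1²)` noise, so the
methylation signal dominates the residual variance (a signal-dominated,
"moderate noise" regime).

All randomness flows through base R's Mersenne-Twister via `set.seed()`;
each generator stage derives its seed from the configuration seed by a fixed
small offset, so outputs are bit-reproducible across platforms.

## The sixteen normalisation strategies

Nine methods follow a three-letter code: `d`/`n` for background adjustment;
`s`/`t`/`n` for between-array quantile normalisation of Type I and II probes
separately, together, or not at all; `s`/`t`/`n` for dye-bias correction.
The registry pins `nasen, dasen, naten, daten1, daten2, nanet, danet, nanes,
danes` plus `raw, swan, noob, bmiq, pbc, tost, funnorm`. Where the published
nomenclature leaves implementation latitude, the package makes these
documented choices:

* **Background adjustment (`d`)**: per sample and signal, Type I
  intensities are shifted additively so their 5th percentile matches the
  Type II 5th percentile, floored at zero. The 5th percentile is a robust
  background statistic; the goal (removing the Type I/II offset) is fixed,
  the estimator is ours.
* **Dye-bias correction**: per-sample quantile equalisation of the red and
  green channel distributions (each value moves to the mean of itself and
  the rank-matched quantile of the other channel), pooled across design
  types (`t`) or within type (`s`). Being per-sample, it never couples a
  sample to its cohort.
* **Between-array QN**: ranks map to the mean order statistic across
  samples; average ranks on ties, tied values mapped to the mean of the
  tied targets. `daten1` normalises the M and U matrices separately;
  `daten2` pools them into one pass — the one degree of freedom the
  nomenclature leaves open, pinned here as the variant flag. Note the
  postcondition differs accordingly: `daten1` makes each matrix's sorted
  columns identical, `daten2` the stacked matrix's.
* **SWAN**: per sample, equal numbers of Type I and II probes per
  CpG-content stratum form the subset; the two design types' subset
  quantile distributions are averaged and all probes are interpolated onto
  it, with additive tail extension beyond the subset range. The "random"
  subset draw is seeded by a hash of the sample id and stratum, which makes
  the method exactly sample-wise — a sample's output cannot depend on which
  other samples are loaded.
* **BMIQ**: per sample and design type, a 3-state beta mixture is fitted by
  EM (initialised at state means 0.1/0.5/0.9, moment-matching M-steps, at
  most 200 iterations, relative log-likelihood tolerance 1e-5; because
  moment-based M-steps plateau rather than strictly ascend, any
  non-improvement after a 10-iteration burn-in also ends the fit). Betas
  are clipped to [1e-6, 1−1e-6] beforehand. Outer-state Type II probes map
  through `pbeta`/`qbeta` onto the Type I fitted components; middle-state
  probes rescale linearly between the transformed boundaries, preserving
  order and continuity. A failed fit leaves that sample unnormalised, with
  a warning.
* **PBC**: per sample, kernel-density peaks (Silverman bandwidth, 512-point
  grid) of negative and positive M-values per design type; Type II
  M-values rescale linearly per side to match the Type I peaks. A peakless
  side is skipped with a warning.
* **Noob**: per sample and channel, background mean/SD estimated from the
  Type I out-of-band readings of the opposite-channel probes, then a
  normal-exponential posterior-mean correction (via `limma`'s normexp
  machinery, strictly positive). Dye equalisation scales the two channels
  to a common level estimated from Type I probes only, whose M+U total
  lives in a single channel and is independent of methylation — using all
  probes would conflate average methylation with dye bias.
* **Funnorm**: control summaries are quantiles/means/SDs of the out-of-band
  background per channel (the published array-specific control-probe set is
  not reproducible off-array), z-scored and reduced by PCA; per design type
  and signal, sample quantile functions are regressed on the leading
  components and the fitted technical effect removed (monotonicity enforced
  by a running maximum), then values re-interpolated. `n_pcs = 0` is the
  identity up to interpolation.
* **Tost**: Type I probes are quantile-normalised across samples; Type II
  intensities are quantile-mapped per sample onto the Type I anchor
  distribution within each CpG-content stratum (empty strata merge
  downward).

Every method returns betas in [0, 1]; beta = M/(M+U+100) and
M-value = log2((M+eps)/(U+eps)) with eps = 1 (the conventional constants —
the analysis depends on differences between arms, not on these offsets).

## Quality metrics

* **DMRSE** = SD of imprinted-DMR betas / sqrt(n samples). The default
  pools probes and samples into one SD; a `per_probe` flag computes
  per-probe SDs first and averages, since the verbal definition is
  ambiguous between the two. The pooled form is the default because it is
  the direct reading of "the standard deviation of DMR beta values".
* **GCOSE**: per SNP probe, 1-D k-means with k = 3 initialised at
  0.1/0.5/0.9; the three within-cluster MSEs (about the fitted centres) are
  averaged, then averaged over probes. Probes with fewer than three
  distinct values are skipped with a warning.
* **Seabird**: the per-sample predictor is the mean beta over X-linked
  probes (the published metric does not pin the classifier; the mean is the
  simplest sex-separating statistic), scored as the female-vs-male AUC by
  the Mann–Whitney rank formula, ties counting one half. Orientation is
  fixed (females positive) rather than folded with `max(AUC, 1−AUC)`, so a
  sign-inverting pathology would be visible. Metric tables store
  `1 − AUC` so that lower is better for all three columns; ranks are
  ascending with average ties, and methods are ordered by mean rank.

## EpiScore training, projection and de-scaling

The training target is the residual of `log(BMI)` on age, sex and the
ancestry covariates (OLS). Features are M-values, optionally pruned to the
`top_k_sd` most variable probes (deterministic ties by probe id). The
elastic net (`alpha = 0.5`) is fitted by `glmnet` with a seeded 10-fold
cross-validation; the model keeps the coefficients at the MSE-minimising
lambda, plus the training means of its probes so that projection onto data
missing some model probes can impute them (more than 20% missing is an
error by default). Projection accepts either value scale but the model
declares its training scale; supplying betas to an M-value model converts
with a warning rather than failing, since the mismatch is common and
detectable. De-scaling inverts the residualisation
(`BMI = exp(score + covariate prediction)`); on a training sample this
reproduces the observed BMI exactly, and for small score differences the
delta method gives `ΔBMI ≈ BMI·Δscore`. The exact published de-scaling
derivation is not available to this package; the inversion above is our
documented approximation.

## The robustness experiment

`separate_vs_joint()` fixes the probe space to the harmonised intersection
*before* either arm, so arm differences reflect normalisation alone, not
probe-set differences; the joint arm subsets the target's samples after
normalising the combined data. `full_benchmark()` loops the registry
fail-soft (one method's failure is recorded, the sweep continues), computes
the three metrics on the jointly normalised data, and is bit-reproducible
under a fixed seed. Percentiles are `100·(rank − 0.5)/n` with average ranks
on ties. Correlations are reported for both arms, since either could be the
analyst's deployed configuration.

## Problem sizes and numerical choices

The default fixture is 5,000 probes by 200+200 samples — a desk-scale
stand-in chosen so that the full within-array invariance check runs in
about a minute; the EpiScore recovery experiment uses 2,000 probes, 500
training samples and 50 causal CpGs; the reproducibility check runs the
full 16-method sweep at 1,200 probes by 40+40 samples twice and compares
byte-for-byte. Interpolation uses `stats::approx` with boundary rule 2 and
mean-collapsed ties throughout; all intensity outputs are floored at zero;
beta outputs are clipped to [0, 1] after back-transformation.

## Known limitations

Within-array invariance and dye-bias sensitivity are structural claims and
transfer to real data; the specific MAD magnitudes, metric values and
recovery correlations do not — they are functions of the generator's SNR
choices. The Funnorm control summaries are a stand-in for the array's
control probes; BMIQ's moment-based EM is a simplification of the original
profile-likelihood fit; and no attempt is made to reproduce any published
implementation's numerical output.
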