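---
title: "Models and methods in fclssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fclssm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it
implements: the isotope-based trophic metrics, the state-space trend
model, the cross-correlation and community-change tools, the synthetic
data they are validated against, and the design choices made where
more than one defensible option existed.

## 1. Trophic metrics from amino-acid δ¹⁵N

### The estimators

A consumer's "trophic" amino acids (glutamic acid, alanine, proline)
gain δ¹⁵N at a trophic discrimination factor (TDF, ‰ per step) with
each transfer, while its "source" amino acids (phenylalanine, glycine)
retain the δ¹⁵N of the nitrogen baseline. Food chain length is

$$FCL = \frac{\delta^{15}N_{Trp} - \delta^{15}N_{Scr} - \beta}{TDF} + 1,$$

with β (‰) the trophic–source offset already present in primary
producers. `fcl_glu_phe()` applies this to the canonical Glu–Phe pair.
`fcl_trp_scr()` is the robust variant: δ¹⁵N_Trp and δ¹⁵N_Scr are
inverse-variance weighted means over the measured trophic and source
AAs,

$$\bar{x}_W = \frac{\sum_x \delta^{15}N_x / \sigma_x^2}
                   {\sum_x 1/\sigma_x^2},$$

where σ_x is the per-AA procedural reproducibility SD (defaults 0.24,
0.08, 0.25, 0.13, 0.19 ‰ for Glu, Ala, Pro, Phe, Gly), and β and TDF
are likewise replaced by 1/SD²-weighted means of the per-pairing
calibration constants over the pairings whose AAs are present.

Both estimators depend only on trophic-minus-source differences, so
they are invariant to any uniform shift of a profile's δ¹⁵N values —
a property the test suite asserts.

### Calibration constants are data

β and TDF come from external feeding-experiment calibrations and vary
across studies; they are therefore stored in `calib_constants()` (and
overridable from YAML via `read_calibration()`), never hard-coded. The
defaults centre on the widely used Glu–Phe values β = 3.6 ‰
(SD 0.5) and TDF = 5.7 ‰ (SD 0.3); the other pairings carry
representative values with larger SDs, so the weighted constants are
dominated by the better-constrained pairs. Any serious application
should substitute the calibration of its own study system. The
weighting of the constants themselves mirrors the 1/σ² form used for
the isotope values; which uncertainties weighted the constants is one
of the genuinely open choices, and using the calibration SDs is this
package's documented decision.

### Efficiency, protist index, and edge cases

With a constant gross growth efficiency per step (GGE, default 0.20 —
a mid-range value for protozoans, metazoan zooplankton and larval
fish), the fraction of base energy reaching trophic level FCL is
`transfer_efficiency(fcl, gge) = gge^(fcl - 1)`; log₁₀ efficiency is
linear in FCL with slope log₁₀(GGE). The temporal pattern, not the
absolute level, is the scientifically robust part: a different but
constant GGE rescales the series without reordering it.

`protist_index()` regresses δ¹⁵N_Ala on δ¹⁵N_Glu by OLS over a cohort
and returns the Ala residuals: alanine is enriched by heterotrophic
protists while glutamic acid is not, so positive residuals indicate a
longer protistan pathway. Residuals are kept in ‰ (a z-scored variant
is available via `standardize = TRUE`).

Deliberate edge-case behaviour:

* FCL < 1 is returned, not clipped, with a warning — negative trophic
  steps flag data problems the analyst must see.
* Specimens missing some AAs have weights renormalised over the AAs
  present and are flagged `"partial"` rather than dropped;
  `fcl_table(complete_only = TRUE)` reproduces a complete-profiles-only
  analysis.
* The optional inclusive 18–23 mm standard-length filter (`sl_range`)
  reproduces a typical specimen-selection window for late-stage larvae.

## 2. The Bayesian random-walk state-space model

### Model and sampler

Annual metrics arrive as replicate measurements in some years and none
in others. `fit_ssm()` models them as

$$x_t = x_{t-1} + w_t, \quad w_t \sim N(0, Q)$$
$$y_{i,t} = x_t + v_{i,t}, \quad v_{i,t} \sim N(0, R)$$

on the full year grid, so missing years are interpolated by the latent
walk with honestly inflated uncertainty. Because the model is
linear-Gaussian with conjugate priors, a Gibbs sampler is exact in
structure: each sweep (i) draws all states jointly by forward-filter
backward-sampling (FFBS) given (Q, R), treating no-observation years
as pure prediction steps, and (ii) draws Q and R from their
inverse-gamma full conditionals given the states. The sweep is
implemented in compiled code (Rcpp) using R's RNG, so fits are
bit-identical under a fixed seed. The correctness anchor is an
independently implemented Kalman smoother in the test helpers — itself
validated against direct joint-Gaussian conditioning on a small
instance — whose exact posterior means and variances the Gibbs draws
must reproduce at fixed (Q, R).

### Priors, defaults, diagnostics

Priors are weakly informative conjugate defaults, all overridable in
`ssm_config()`: inverse-gamma(0.01, 0.01) on Q and R, and
N(mean of the first observed year, 10 × sample variance) on x₁.
Defaults of 3 chains × 20,000 iterations, 5,000 burn-in, thinning 5
(9,000 pooled draws) reach split-chain R̂ ≤ 1.05 on the reference
synthetic fits in well under a minute on one CPU; variance inits are
overdispersed across chains so R̂ is an honest diagnostic. Any R̂
above the threshold raises a warning and a `converged = FALSE` flag,
never a silent pass. A series whose observations are all identical
makes R unidentifiable; the fit refuses it and advises the
`fix_R` fallback (also used for exact-inference checks and noiseless
limits).

The observation distribution is taken as normal; series spanning
orders of magnitude (size ratios, biomasses, abundances) can be fitted
on the natural-log scale via `log_scale = TRUE`, the package's
recommendation for such series, while the default remains the natural
scale.

### MAP series

"Yearly MAP value" has no unique recipe from MCMC output. The package
defines it as the mode of a Gaussian-kernel density estimate
(Silverman's rule-of-thumb bandwidth, `stats::density` defaults) over
the pooled per-year draws, with the posterior median reported
alongside — a large MAP–median gap is itself a skewness diagnostic.
Intervals are central 2.5–97.5% quantiles. Degenerate draw sets
(zero variance) return the point mass directly; fewer than 200 pooled
draws are refused.

## 3. Cross-correlation of MAP series

`ccf_annual()` computes, at lag k, the Pearson correlation of
(x_{t+k}, y_t) over the overlapping years — positive lags mean x leads
y. The orientation is fixed and written into every output header
because lag-sign conventions differ across software and are a classic
source of silent errors. Each lag uses its own pairwise-complete
overlap; lags with fewer than 3 pairs are reported missing, never
zero. The accompanying band ±1.96/√n (≈ ±0.29 at n = 45, i.e. the
familiar "about ±0.30") is the exceedance level a white-noise pair
would reach 5% of the time; the test suite calibrates it by Monte
Carlo. For series that were interpolated by the state-space model the
band is descriptive only — interpolation induces smoothness that
violates the independence a significance test would need — so the
package deliberately attaches no p-values.

## 4. Community change detection

Abundance matrices are transformed as ln(a + 1) — the offset keeps
zero abundances defined and is configurable — and converted to
Bray–Curtis dissimilarities (via vegan). `chronological_cluster()`
then performs agglomerative clustering in which only temporally
adjacent clusters may merge, with the incremental sum-of-squares
criterion of stratigraphically constrained clustering: a cluster's
dispersion is Σ d²(within pairs)/size, and each step makes the
adjacent merge with the smallest dispersion increase. An all-zero pair
of years has an undefined Bray–Curtis quotient and is defined as 0
(identical communities) with a warning.

Zone-count selection is intentionally not automated: the analyst who
chose this method judges "deep breaks" from the merge profile. The
package reports the full increment/height sequence, offers a
largest-increment suggestion, and lets `zones(x, k)` cut at any count.
The two-block oracle test guarantees that the first deep break
coincides with the exhaustive-search optimal contiguous 2-partition.
z-scoring (`zscore_series()`) uses the n−1 sample SD.

## 5. The synthetic-data generator

`simulate_coupled_system()` emulates the statistical structure of the
observational design, not any real dataset:

* a 45-year window (default 1961–2005) with ~45% of years carrying
  specimens (about 20 of 45), 3–15 specimens per sampled year;
* a latent FCL random walk (Q_fcl = 0.01 TL²/yr around a start of
  3.2) and a latent source-δ¹⁵N walk (Q = 0.04 ‰²/yr around 8 ‰);
* specimen AA profiles from the forward model of the FCL equation —
  source AAs at the baseline, trophic AAs one β + TDF·(FCL−1) above
  it — with per-AA procedural noise at the published SDs and a
  specimen-level trophic spread (SD 0.3 TL); noiseless simulation
  inverts exactly through `fcl_trp_scr()`, the package's round-trip
  oracle;
* a log size-ratio walk whose innovations share the FCL innovations
  with loading +0.8, and a log-SSB walk whose innovations load on the
  previous year's size-ratio innovation with −0.6 — constructive
  coupling, so the innovation correlations are exact in expectation.
  Note that the finite-window correlation of the resulting *paths* is
  attenuated below the innovation loading (empirically ≈ 0.72 at
  n = 45 for a loading of 0.8) because both walks are demeaned over a
  short window; tests therefore assert the innovation correlation at
  its target and a strong positive path correlation, not equality of
  the two;
* an optional boom-bust step (e.g. +0.5 TL and −2.5 ‰ at 1988) that
  enters the shared innovations — so coupled series inherit the regime
  shift — and plants a community break: six "small copepod" taxa
  collapse to 35% of their pre-break mean while a large calanoid
  gains, under lognormal year-to-year noise.

Magnitudes without an observational anchor (Q/R values, step sizes,
community shift factors) are package choices of realistic order, made
once and documented here; they are configuration, not ground truth.
What passing tests on these data do **not** show: robustness to
non-Gaussian observation errors, preservation artefacts, spatially
structured sampling, taxonomic reassignments, or baseline shifts that
violate the constant-β/TDF assumption. Real CalCOFI-style data have
all of these.

## 6. Numerical choices and problem sizes

* FFBS uses precision-form updates; the R residual sum of squares is
  guarded against floating-point cancellation. `fix_R = 1e-12`
  reproduces the noiseless observation limit to 1e-6.
* Constrained clustering breaks ties toward the earlier merge
  (`which.min`); taxon column order provably does not affect results.
* Size-ratio bins are half-open [5, 10) and [10, 20) mm so a 10 mm
  larva is counted exactly once (as large); zero small-larva years
  become missing, never infinite.
* FCL values within 1e-9 below 1 are not warned about (floating-point
  guard); genuinely smaller values are.
* The end-to-end recovery test measures the planted FCL step by
  contrasting the MAP series with the no-step latent baseline (truth
  used only as an oracle); this removes random-walk drift, which would
  otherwise dominate a naive pre/post window contrast.
* Test-suite problem sizes: reference fits use T = 45 with 40%
  missing years and 5 replicates/year at default sampler settings;
  exact-smoother checks use T = 10 with 12,000–22,000 unthinned
  iterations; coverage uses 50 replicate fits at 4,000 iterations;
  Monte-Carlo calibrations use 100–1,000 replicates. These sizes give
  each check enough resolution for its stated tolerance while keeping
  the full suite around half a minute.

## 7. Known limitations

* Uncertainty in β/TDF is not propagated into per-specimen FCL
  standard errors; yearly uncertainty comes from the state-space
  model's R.
* One state-space model per series: no joint multivariate fit, no
  trend or higher-order autoregressive latent dynamics, no
  non-Gaussian observation families.
* Cross-correlations on interpolated MAP series are descriptive;
  the package refuses to dress them as hypothesis tests.
* The GGE-based efficiency conversion is a monotone transform of FCL;
  its absolute level is only as good as the constant-GGE assumption.
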