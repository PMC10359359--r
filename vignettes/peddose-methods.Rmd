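---
title: "Methods: pediatric DLP-to-effective-dose coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric DLP-to-effective-dose coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peddose)
```

## The model

Effective dose for a CT scan is the ICRP Publication 103 tissue-weighted
sum of organ equivalent doses, `E = Σ_T w_T H_T` (mSv). The weight set —
0.12 for red bone marrow, colon, lung, stomach, breast and the pooled
remainder; 0.08 for gonads; 0.04 for bladder, oesophagus, liver, thyroid;
0.01 for bone surface, brain, salivary glands, skin — sums to one, so a
uniform organ dose *d* yields `E = d`. Two modelling simplifications are
baked in: photon radiation only (radiation weighting factor 1, so
equivalent dose equals absorbed dose numerically), and the 13-tissue ICRP
remainder is pooled into a single label carrying a caller-supplied mean
remainder dose. Organ-dose computation itself (Monte Carlo transport
through anatomical phantoms) is out of scope; where reference effective
doses appear they are inputs.

The quantity the package derives and applies is the conversion coefficient

```
k = E_reference / DLP        (mSv per mGy·cm)
```

summarized per stratum by its median and 25th/75th percentiles. Strata are
body region crossed with any of: age group (`<1`, `1–4`, `5–9`, `10–14`,
`15–21` years), patient mean-effective-diameter bin (5-cm bins, 11–40 cm),
and scanner manufacturer. Head and neck scans are never stratified by
diameter, because their reference doses are age-matched only. Applying a
table inverts the ratio: `E ≈ k_stratum_median × DLP`.

## Binning and lookup conventions

Both binnings are half-open with the boundary going to the upper bin: an
exactly 1-year-old is `1–4`, a 16.0-cm diameter is `16–20`. This makes the
bins a partition (every in-range value maps to exactly one bin), which is a
choice — the published table headers do not pin down the edge convention.
The oldest group's upper edge is age < 22, consistent with a registry that
samples 18–21-year-olds. Diameters outside [11, 41) cm clamp to the nearest
bin with a warning rather than erroring: real registries contain such
scans, and refusing them would silently bias any downstream summary.
Coefficient lookup always returns the stratum *median*; the IQR is carried
for uncertainty reporting, never sampled from. Diameter-containing lookup
strategies fall back to age for head/neck scans with a logged notice.

## Exclusion cascade

`apply_exclusions()` applies, in order: (1) perfusion scans; (2) missing or
erroneous records — missing region/age/DLP, non-positive DLP, CTDI-vol,
diameter or scan length, age outside [0, 22); (3) two-tail percentile
trimming (default 1% per tail) on CTDI-vol, DLP, diameter, scan length,
reference dose and mAs. Three decisions here were genuinely open and are
fixed as follows. Trim quantiles are computed *globally* on the
post-step-2 set, not per region (a per-region mode exists behind
`per_region = TRUE`); the trim is applied *jointly*, all six variables
against the same reference quantiles, rather than sequentially re-computing
quantiles after each variable; and a record exactly equal to a trim
boundary is retained — only strictly outside values are removed, which is
conservative and deterministic under ties. Each removed record is counted
under the first rule that caught it, so the exclusion log reconciles
exactly: retained + Σ counts = input. Records missing an optional trim
variable (e.g. head scans without a recorded diameter) are exempt from that
variable's trim. Age-band subsampling (`subsample_age_band()`) uses
per-record Bernoulli draws under a fixed seed rather than an exact-count
sample: the retained count is then binomial, which tests account for.

## Stratified derivation

`derive_coefficients()` computes per-stratum median and quartiles of the
per-scan `k` with the type-7 percentile definition (linear interpolation
between order statistics, R's default). Other statistical environments
default to different quantile types; medians are unaffected and quartile
differences are negligible at registry sample sizes, but the definition is
exposed via `quantile_type`. Strata with fewer than `min_n = 10` scans are
omitted entirely — never zero-filled — so a sparse stratum (e.g. spine
under 1 year) is a *missing-stratum* condition at lookup time, not a zero.
Relative coefficients (youngest/oldest or smallest/largest stratum medians
per region) are rounded half-away-from-zero to one decimal, the convention
that reproduces published one-decimal ratios; the unrounded value is always
returned alongside. When a region's extreme stratum is suppressed, the
extreme *available* stratum is used (spine: `1–4` vs `15–21`).

## Agreement metrics

Agreement between DLP-derived and reference doses is summarized per region
and lookup strategy by (a) the Pearson correlation with a 95% Fisher-z
interval (`atanh(r) ± 1.96/√(n−3)`, back-transformed; degenerate at
|r| = 1) and (b) the percentage of scans whose relative error
`|E_est − E_ref| / E_ref` meets or exceeds 0.5. The reference dose is
always the denominator. The threshold comparison is `≥` by default
(`strict = TRUE` gives `>`): the two readings differ only on the
measure-zero boundary and the inclusive one is adopted. Scans whose stratum
is absent from a table are excluded from that row's statistics and reported
in `n_unmatched` — they are information about table coverage, not about
estimator error. Legacy single-reference-age coefficient sets are applied
through an explicit age-label mapping (`legacy_age_map()`); legacy values
themselves are user input, not packaged.

## The synthetic registry

`generate_registry()` exists because the registry the coefficient tables
came from is proprietary. It emulates the *statistical structure* the
pipeline relies on, with defaults tied to the packaged composition counts
and coefficient tables:

* **Composition.** Region, and region-conditional age-group, sex and
  manufacturer mixes equal the packaged empirical proportions (head ≈ 53.6%
  of scans, etc.). Age is uniform within its group; 18–21-year-olds are
  generated in full so the subsampling filter can be exercised. Strata
  absent from the true coefficient table (spine `<1`) are never sampled.
* **Size.** Diameter is log-normal with median `11 + 0.8 × age` cm and
  log-scale SD 0.12 — a plausible pediatric growth curve (≈ 11 cm at birth,
  ≈ 28 cm at 21) chosen once; nothing downstream depends on its exact form.
* **Dose.** DLP and scan length are region-specific log-normals whose
  medians grow with age (e.g. head from 400 mGy·cm with a shallow slope,
  abdominal regions steeper), with CTDI-vol defined as DLP/scan length. The
  published material gives no DLP distributions, so these are
  order-of-magnitude plausible and fully config-driven; tests never assert
  specific DLP locations.
* **Reference dose.** `E_ref = k_true(stratum) × DLP × exp(σZ)` with
  standard-normal *Z*. Multiplicative log-normal noise is the natural
  choice for a ratio quantity with right-skewed spread, and its median is
  exactly 1, so stratum medians of `E_ref/DLP` are median-unbiased for
  `k_true` — which is what makes median recovery a clean test. The default
  σ is *calibrated*, not tuned: it is the value implied by the published
  IQR ratios, `median(log(q75/q25)) / (2·Φ⁻¹(0.75)) ≈ 0.41`, so the
  simulated per-scan coefficient spread matches the published spread (e.g.
  head `<1`: 0.045/0.026 ≈ 1.73). Diameter influences `E_ref` only through
  optional stratified modulation of `k_true` (`diameter_effect = TRUE`,
  using the published diameter medians normalized per region), mirroring
  the stratified representation rather than a continuous attenuation model.
* **Blemishes.** Perfusion flags (0.5%) and missing DLP/age/diameter
  (0.2–1%) are injected so the exclusion filters have work to do; head/neck
  diameters are absent by default. Sex is sampled but does not influence
  dose, as no sex-specific coefficients are derived.

What passing tests on this generator do **not** show: fidelity to real
anatomy (no phantom morphometry, no tube-current modulation, no
beam-hardening physics), real DLP distributions, or the heavy-tailed
artifacts of production DICOM feeds. They show that the *pipeline
arithmetic* — filtering, stratified estimation, lookup, agreement — is
correct and recovers known generating parameters.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::with_seed`),
and a registry is bit-identical for a fixed configuration. The test suite
and acceptance script use sizes chosen to make the statistical assertions
sharp while keeping runs fast: 2,000 scans per stratum for median recovery
(log-scale SE of a stratum median ≈ 1.25·σ/√n ≈ 1.2%, comfortably inside
the 5% recovery tolerance), 10,000 per stratum for the bias check, 30,000–
50,000 scans for composition and report-structure checks (large enough that
the rarest region, cardiac at ≈ 0.4%, clears the min-n rule in age strata),
and 100,000 for the end-to-end loop.

## Known limitations

* Coefficients are raw stratum medians; no smoothing or regression across
  age or diameter, so estimates jump at bin edges.
* The registry-scale correlations and error percentages published for the
  original cohort depend on its per-scan Monte Carlo doses and cannot be
  recomputed here; the synthetic pipeline reproduces their *structure* and
  the properties that drive them (noise up → correlation down, error rate
  up; age+diameter strata ≥ age-only on diameter-dependent data).
* Reporting-phantom size (16 vs 32 cm) is carried for audit only;
  coefficients are not derived separately by phantom.
* The one-decimal relative-coefficient rounding uses a 1e-9 nudge to
  absorb binary floating-point representation of decimal ratios; ratios
  within 1e-9 of a half-way point round up by design.
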