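# peddose

Pediatric CT dosimetry: DLP-to-effective-dose conversion coefficients and
the pipeline around them.

## The problem

Effective dose *E* (mSv) — the ICRP-103 tissue-weighted sum of organ
equivalent doses, `E = Σ_T w_T · H_T` — is the standard whole-body summary
of a CT scan's stochastic cancer-risk burden, but computing it properly
requires Monte Carlo radiation transport through an anatomical phantom. In
routine practice it is instead approximated from the scanner-reported dose
length product (DLP, mGy·cm) through a scalar conversion coefficient
(*k*-factor):

```
E ≈ k(region, age | diameter) × DLP        [k in mSv per mGy·cm]
```

For children the coefficient varies enormously — roughly 4- to 13-fold
between infants and late adolescents depending on the body region — so a
single adult coefficient is badly wrong. `peddose` implements the analysis
pipeline that turns a registry of per-scan dose records into
region × age-group (and region × diameter-bin, region × manufacturer)
coefficient tables, applies them, and quantifies how well the resulting
DLP-derived doses agree with reference (Monte-Carlo-style) doses. It is
aimed at medical-physics and radiation-epidemiology users who maintain dose
registries or need defensible pediatric *k*-factors.

The package provides:

* **Dose arithmetic** — ICRP-103 weights (`icrp103_weights()`,
  `effective_dose()`), per-scan coefficients (`scan_coefficient()`),
  age/diameter binning, coefficient lookup and `dlp_derived_dose()`.
* **Registry handling** — delimited-table ingestion with column mapping
  (`read_scan_table()`), the study-style exclusion cascade (perfusion scans,
  missing/erroneous records, 1% two-tail trimming on six dose variables;
  `apply_exclusions()`), and seeded age-band subsampling
  (`subsample_age_band()`).
* **Coefficient derivation** — stratified median/IQR tables with a
  ≥ 10-scans-per-stratum rule (`derive_coefficients()`) and relative
  coefficients across the extreme strata (`relative_coefficient()`).
* **Agreement metrics** — Pearson correlation with Fisher-z intervals,
  percentage of scans with ≥ 50% relative error, legacy-coefficient
  comparison, and a region × strategy report (`agreement_report()`).
* **A synthetic registry generator** (`synthetic_config()`,
  `generate_registry()`) that reproduces the published registry's region,
  age, sex and manufacturer composition and its coefficient levels and
  spreads, so the whole pipeline is testable without proprietary data.
* **Published tables** — the region × age and region × diameter coefficient
  tables (`published_k_by_age()`, `published_k_by_diameter()`) and the
  registry composition counts (`registry_counts()`) ship as plain-CSV data.

## Worked example

```r
library(peddose)

# A 6-month-old's head CT with DLP = 312 mGy·cm:
k <- lookup_coefficient(published_k_by_age(), "head", age = 0.5, strategy = "age")
k
#> [1] 0.039
dlp_derived_dose(312, k)
#> [1] 12.168     # mSv

# Full loop on a synthetic registry:
cfg  <- synthetic_config(n_scans = 30000, seed = 42)
reg  <- generate_registry(cfg)
filt <- apply_exclusions(reg)
filt$log
#> Exclusion log: 30000 in, 26979 retained
#>   perfusion: 153
#>   missing_fields: 135
#>   tail_trim:ctdi_vol: 596
#>   ...
tab <- derive_coefficients(filt$scans, axes = "age_group")
print(tab, n = 2)
#> <coefficient table: 31 strata; axes beyond region: age_group>
#>   body_region age_group ... median_k   q25_k  q75_k     n
#> 1 head        <1            0.0381   0.0279  0.0513  1114
#> 2 head        1-4           0.0131   0.00964 0.0176  2698
agreement_report(filt$scans, list(age = tab))[, c(1, 3, 5, 8)]
#>   body_region     n pearson_r pct_gt_threshold
#> 1 head        14703     0.858             22.7
#> 2 neck         2302     0.759             22.5
#> ...
```

The derived head `<1` median (0.0381 mSv/mGy·cm, against a generating value
of 0.039) illustrates parameter recovery; the correlation and the ~23% of
scans off by ≥ 50% show what a single age-group coefficient can and cannot
promise for an individual scan.

A command-line wrapper with `simulate` / `filter` / `derive` / `estimate` /
`agree` subcommands is installed at
`system.file("scripts", "peddose", package = "peddose")`; every run writes a
JSON manifest beside its outputs.

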