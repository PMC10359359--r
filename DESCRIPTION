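Package: peddose
Title: Pediatric CT Effective Dose Coefficients and DLP-Derived Dose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying dose-length-product (DLP) to
    effective-dose conversion coefficients (k-factors) for pediatric computed
    tomography. Implements ICRP Publication 103 tissue-weighted effective dose
    aggregation, per-scan coefficient computation, stratified (body region by
    age group, patient diameter bin, and scanner manufacturer) median/IQR
    coefficient tables with a minimum-stratum-size rule, registry-style
    inclusion/exclusion filters with percentile tail trimming, DLP-derived
    effective dose estimation via coefficient lookup, and agreement metrics
    (Pearson correlation with Fisher-z intervals, fraction of scans exceeding a
    relative-error threshold) against reference Monte-Carlo-style doses. A
    seed-reproducible synthetic registry generator emulates the statistical
    structure of a multicenter pediatric CT dose registry so the full pipeline
    is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
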