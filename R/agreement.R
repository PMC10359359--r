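#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation between two dose series with a
#' `1 - alpha` confidence interval computed on the Fisher z scale
#' (`atanh(r) +/- z * 1/sqrt(n - 3)`, back-transformed).
#'
#' @param x,y Equal-length numeric series with finite values and non-zero
#'   variance; `n >= 3`.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return List with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    peddose_abort("series must have equal length", "parameter")
  }
  if (length(x) < 3) {
    peddose_abort("need at least 3 paired observations", "insufficient_data")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    peddose_abort("series must be finite", "domain")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    peddose_abort("zero variance in a series", "degenerate_input")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 || n == 3) {
    # Fisher z is unbounded at |r| = 1; the interval degenerates
    lo <- hi <- r
    if (n > 3 && abs(r) < 1) {
      z <- atanh(r); se <- 1 / sqrt(n - 3); q <- qnorm(1 - alpha / 2)
      lo <- tanh(z - q * se); hi <- tanh(z + q * se)
    }
  } else {
    z <- atanh(r); se <- 1 / sqrt(n - 3); q <- qnorm(1 - alpha / 2)
    lo <- tanh(z - q * se); hi <- tanh(z + q * se)
  }
  list(r = r, ci_low = lo, ci_high = hi, n = n)
}

#' Percentage of scans exceeding a relative-error threshold
#'
#' Fraction (as a percentage) of scans whose estimated dose differs from the
#' reference dose by at least `threshold` of the reference:
#' `100 * mean(|estimate - reference| / reference >= threshold)`. The
#' reference (Monte-Carlo-style) dose is always the denominator. Scans with
#' a missing estimate (unmatched stratum) are excluded from the percentage
#' and counted separately.
#'
#' @param estimate Estimated dose series, mSv (`NA` allowed).
#' @param reference Reference dose series, mSv; strictly positive.
#' @param threshold Relative-error threshold as a proportion (default 0.5).
#' @param strict Use a strict `>` comparison instead of the default `>=`.
#' @return List with `pct`, `n` (scans compared), `n_missing`, `threshold`.
#' @export
pct_relative_error_above <- function(estimate, reference, threshold = 0.5,
                                     strict = FALSE) {
  if (length(estimate) != length(reference)) {
    peddose_abort("series must have equal length", "parameter")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    peddose_abort("threshold must be positive", "parameter")
  }
  if (any(is.na(reference)) || any(reference <= 0)) {
    peddose_abort("reference doses must be strictly positive", "domain")
  }
  ok <- !is.na(estimate)
  rel <- abs(estimate[ok] - reference[ok]) / reference[ok]
  hit <- if (strict) rel > threshold else rel >= threshold
  list(pct = if (sum(ok) > 0) 100 * mean(hit) else NA_real_,
       n = sum(ok), n_missing = sum(!ok), threshold = threshold)
}

#' Age-label mapping for legacy single-age coefficient sets
#'
#' Maps the reference-age labels of legacy coefficient sets (one coefficient
#' per region at a handful of phantom reference ages, the form older
#' k-factor publications take) onto the five study age groups: "0 year old" covers `<1`, "1 year old"
#' covers `1-4`, "5 years old" covers `5-9`, "10 years old" covers `10-14`,
#' and "adult" covers `15-21`.
#'
#' @return Named character vector, legacy label to age group.
#' @export
legacy_age_map <- function() {
  c("0 year old" = "<1", "1 year old" = "1-4", "5 years old" = "5-9",
    "10 years old" = "10-14", "adult" = "15-21")
}

#' Apply a legacy coefficient set to a scan table
#'
#' Computes per-scan DLP-derived doses using a user-supplied legacy
#' coefficient set: each scan's `(region, age group)` is resolved to a
#' legacy reference-age coefficient through `age_map` and multiplied by the
#' scan's DLP. Legacy coefficient values are inputs, not packaged.
#'
#' @param scans Tibble of scan records.
#' @param legacy Data frame with columns `body_region`, `age_label`, `k`.
#' @param age_map Named character vector mapping `age_label` to age group;
#'   default [legacy_age_map()].
#' @return Numeric vector of doses (mSv) aligned with `scans`.
#' @export
apply_legacy_coefficients <- function(scans, legacy, age_map = legacy_age_map()) {
  need <- c("body_region", "age_label", "k")
  if (!all(need %in% names(legacy))) {
    peddose_abort("legacy set needs columns body_region, age_label, k",
                  "parameter")
  }
  legacy$age_group <- unname(age_map[legacy$age_label])
  if (any(is.na(legacy$age_group))) {
    peddose_abort("legacy age label(s) not covered by the age map",
                  "missing_mapping")
  }
  ok_age <- !is.na(scans$age) & scans$age >= 0 & scans$age < 22
  if (!all(ok_age)) {
    peddose_abort("scan ages must lie in [0, 22)", "domain")
  }
  key <- paste(scans$body_region, assign_age_group(scans$age), sep = "|")
  lkey <- paste(legacy$body_region, legacy$age_group, sep = "|")
  m <- match(key, lkey)
  if (any(is.na(m))) {
    miss <- unique(key[is.na(m)])
    peddose_abort(paste0("no legacy coefficient for: ",
                         paste(utils::head(miss, 5), collapse = "; ")),
                  "missing_mapping")
  }
  scans$dlp * legacy$k[m]
}

#' Region-by-strategy agreement report
#'
#' For each body region and each supplied lookup strategy, quantifies
#' agreement between DLP-derived and reference effective doses: Pearson
#' correlation with a 95% Fisher-z interval, and the percentage of scans
#' whose relative error meets or exceeds `threshold`. Head and neck rows are
#' produced only for age-based strategies (their reference doses are
#' age-matched only). Scans whose stratum is missing from a table are
#' excluded from that row and reported in `n_unmatched`.
#'
#' @param scans Tibble of scan records with `e_reference` present.
#' @param tables Named list of `peddose_coef_table`s; names are strategies
#'   among `"age"`, `"diameter"`, `"age_diameter"`, `"manufacturer_age"`.
#' @param legacy Optional legacy coefficient set (see
#'   [apply_legacy_coefficients()]); adds a `"legacy"` strategy.
#' @param threshold Relative-error threshold (proportion, default 0.5).
#' @param alpha Significance level for the correlation interval.
#' @return Tibble with one row per region and strategy: `body_region`,
#'   `strategy`, `n`, `n_unmatched`, `pearson_r`, `ci_low`, `ci_high`,
#'   `pct_gt_threshold`, `threshold`.
#' @export
agreement_report <- function(scans, tables, legacy = NULL, threshold = 0.5,
                             alpha = 0.05) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    peddose_abort("tables must be a named list keyed by strategy", "parameter")
  }
  scans <- scans[!is.na(scans$e_reference) & scans$e_reference > 0 &
                   !is.na(scans$dlp) & scans$dlp > 0, , drop = FALSE]
  rows <- list()
  add_rows <- function(strategy, est, regions) {
    for (reg in regions) {
      i <- which(scans$body_region == reg)
      if (length(i) == 0) next
      e <- est[i]; ref <- scans$e_reference[i]
      ok <- !is.na(e)
      if (sum(ok) < 3 || stats::sd(e[ok]) == 0 || stats::sd(ref[ok]) == 0) next
      pc <- pearson_with_ci(e[ok], ref[ok], alpha = alpha)
      pe <- pct_relative_error_above(e, ref, threshold = threshold)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        body_region = reg, strategy = strategy,
        n = pc$n, n_unmatched = sum(!ok),
        pearson_r = pc$r, ci_low = pc$ci_low, ci_high = pc$ci_high,
        pct_gt_threshold = pe$pct, threshold = threshold)
    }
  }
  for (strategy in names(tables)) {
    regions <- intersect(body_regions(), unique(scans$body_region))
    if ("diameter_bin" %in% strategy_axes(strategy)) {
      regions <- setdiff(regions, no_diameter_regions())
    }
    est <- estimate_effective_dose(scans, tables[[strategy]], strategy)
    add_rows(strategy, est, regions)
  }
  if (!is.null(legacy)) {
    covered <- scans$body_region %in% unique(legacy$body_region)
    est <- rep(NA_real_, nrow(scans))
    if (any(covered)) {
      est[covered] <- apply_legacy_coefficients(scans[covered, , drop = FALSE],
                                                legacy)
    }
    add_rows("legacy", est, intersect(body_regions(), unique(legacy$body_region)))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(body_region = character(), strategy = character(),
                          n = integer(), n_unmatched = integer(),
                          pearson_r = double(), ci_low = double(),
                          ci_high = double(), pct_gt_threshold = double(),
                          threshold = double()))
  }
  dplyr::bind_rows(rows)
}
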