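#' Derive a stratified conversion-coefficient table
#'
#' Computes, for every body-region stratum crossed by the requested axes,
#' the median and 25th/75th percentiles of the per-scan coefficient
#' `k = e_reference / dlp` (mSv per mGy·cm) together with the stratum size.
#' Strata with fewer than `min_n` scans are omitted, never zero-filled.
#' Head and neck scans are never stratified by diameter: when
#' `diameter_bin` is among the axes they are grouped on the remaining axes
#' only, and on a pure-diameter run they are dropped from the table.
#' Scans lacking a value required by an axis (for example diameter on a
#' diameter-axis run) are dropped with a logged count.
#'
#' @param scans Tibble of scan records carrying `e_reference` and `dlp`.
#' @param axes Character subset of `c("age_group", "diameter_bin",
#'   "manufacturer")`; may be empty for a region-only table.
#' @param min_n Minimum scans per reported stratum (default 10).
#' @param quantile_type Percentile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return A `peddose_coef_table`. The number of scans dropped for missing
#'   required values is attached as `attr(, "n_dropped")`.
#' @export
derive_coefficients <- function(scans, axes = "age_group", min_n = 10L,
                                quantile_type = 7L) {
  bad_axes <- setdiff(axes, c("age_group", "diameter_bin", "manufacturer"))
  if (length(bad_axes) > 0) {
    peddose_abort(paste0("unknown axis: ", paste(bad_axes, collapse = ", ")),
                  "parameter")
  }
  if (!is.numeric(min_n) || min_n < 1) {
    peddose_abort("min_n must be >= 1", "parameter")
  }
  if (nrow(scans) == 0) {
    peddose_abort("no scans supplied for coefficient derivation", "empty_input")
  }

  df <- tibble::tibble(
    body_region = scans$body_region,
    dlp = scans$dlp,
    e_reference = scans$e_reference
  )
  usable <- !is.na(df$body_region) & !is.na(df$dlp) & df$dlp > 0 &
    !is.na(df$e_reference)
  df$age_group <- NA_character_
  df$diameter_bin <- NA_character_
  df$manufacturer <- NA_character_
  if ("age_group" %in% axes) {
    ok <- !is.na(scans$age) & scans$age >= 0 & scans$age < 22
    df$age_group[ok] <- assign_age_group(scans$age[ok])
    usable <- usable & ok
  }
  if ("manufacturer" %in% axes) {
    df$manufacturer <- scans$manufacturer
    usable <- usable & !is.na(df$manufacturer)
  }
  hn <- df$body_region %in% no_diameter_regions()
  if ("diameter_bin" %in% axes) {
    d <- scans$mean_effective_diameter
    ok <- !is.na(d) & d > 0
    df$diameter_bin[ok] <- suppressWarnings(assign_diameter_bin(d[ok]))
    if (identical(axes, "diameter_bin") || !"age_group" %in% axes) {
      # pure diameter stratification cannot cover head/neck
      usable <- usable & !hn & ok
    } else {
      usable <- usable & (hn | ok)
      df$diameter_bin[hn] <- NA_character_
    }
  }
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    rlang::inform(paste0(n_dropped,
                         " scan(s) dropped from derivation (missing required fields)"),
                  class = "peddose_notice_derivation_drop")
  }
  df <- df[usable, , drop = FALSE]
  if (nrow(df) == 0) {
    peddose_abort("no usable scans for coefficient derivation", "empty_input")
  }
  df$k <- df$e_reference / df$dlp

  grouped <- dplyr::group_by(df, .data$body_region, .data$age_group,
                             .data$diameter_bin, .data$manufacturer)
  out <- dplyr::summarise(
    grouped,
    median_k = quantile(.data$k, 0.5, type = quantile_type, names = FALSE),
    q25_k = quantile(.data$k, 0.25, type = quantile_type, names = FALSE),
    q75_k = quantile(.data$k, 0.75, type = quantile_type, names = FALSE),
    n = dplyr::n(),
    .groups = "drop")
  out <- out[out$n >= min_n, , drop = FALSE]
  if (nrow(out) == 0) {
    peddose_warn("no stratum reached min_n; returning an empty table",
                 "empty_table")
  }
  out <- out[order(match(out$body_region, body_regions()),
                   match(out$age_group, age_group_levels()),
                   match(out$diameter_bin, diameter_bin_levels()),
                   out$manufacturer), , drop = FALSE]
  res <- as_coef_table(out)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Relative coefficient across the extreme strata of a region
#'
#' The ratio of the youngest-available to oldest-available stratum median
#' (age axis) or smallest-available to largest-available (diameter axis),
#' quantifying how strongly the conversion coefficient varies across the
#' pediatric range. The ratio is reported both unrounded and rounded
#' half-away-from-zero to one decimal, the convention used for published
#' tables. Regions whose youngest stratum is suppressed (e.g. spine `<1`)
#' use the youngest stratum actually present.
#'
#' @param table A `peddose_coef_table` stratified along `axis`.
#' @param region Body region.
#' @param axis `"age_group"` or `"diameter_bin"`.
#' @return List with `value` (rounded to one decimal), `unrounded`,
#'   `numerator_stratum` and `denominator_stratum`.
#' @export
relative_coefficient <- function(table, region,
                                 axis = c("age_group", "diameter_bin")) {
  axis <- match.arg(axis)
  other <- setdiff(c("age_group", "diameter_bin", "manufacturer"), axis)
  sel <- table$body_region == region & !is.na(table[[axis]])
  for (a in other) sel <- sel & is.na(table[[a]])
  rows <- table[sel, , drop = FALSE]
  if (nrow(rows) < 2) {
    peddose_abort(paste0("fewer than 2 populated ", axis, " strata for ",
                         region), "insufficient_strata")
  }
  lev <- if (axis == "age_group") age_group_levels() else diameter_bin_levels()
  rows <- rows[order(match(rows[[axis]], lev)), , drop = FALSE]
  num <- rows$median_k[1]
  den <- rows$median_k[nrow(rows)]
  ratio <- num / den
  list(value = round_half_out(ratio, 1),
       unrounded = ratio,
       numerator_stratum = rows[[axis]][1],
       denominator_stratum = rows[[axis]][nrow(rows)])
}
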