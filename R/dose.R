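#' ICRP Publication 103 tissue weighting factors
#'
#' The tissue weighting factor set used to aggregate organ equivalent doses
#' into effective dose: 0.12 each for red bone marrow, colon, lung, stomach,
#' breast and the (pooled) remainder tissues; 0.08 for gonads; 0.04 each for
#' bladder, oesophagus, liver and thyroid; 0.01 each for bone surface, brain,
#' salivary glands and skin. The set sums to 1. The remainder is represented
#' as a single pooled tissue taking a caller-supplied mean remainder dose.
#'
#' @return Named numeric vector of weights.
#' @export
icrp103_weights <- function() {
  c(red_bone_marrow = 0.12, colon = 0.12, lung = 0.12, stomach = 0.12,
    breast = 0.12, remainder = 0.12,
    gonads = 0.08,
    bladder = 0.04, oesophagus = 0.04, liver = 0.04, thyroid = 0.04,
    bone_surface = 0.01, brain = 0.01, salivary_glands = 0.01, skin = 0.01)
}

#' Effective dose from organ equivalent doses
#'
#' Computes the tissue-weighted sum `E = sum_T w_T * H_T` (mSv). Organ
#' equivalent doses are numerically equal to absorbed doses for photon
#' radiation (radiation weighting factor 1). Organs absent from
#' `organ_doses` contribute zero.
#'
#' @param organ_doses Named numeric vector of organ equivalent doses (mSv);
#'   names must be a subset of `names(weights)`.
#' @param weights Tissue weighting factors; default [icrp103_weights()].
#' @return Effective dose in mSv.
#' @export
#' @examples
#' effective_dose(c(lung = 10, thyroid = 5)) # 0.12*10 + 0.04*5 = 1.40
effective_dose <- function(organ_doses, weights = icrp103_weights()) {
  if (length(organ_doses) == 0) return(0)
  if (is.null(names(organ_doses)) || any(!nzchar(names(organ_doses)))) {
    peddose_abort("organ doses must be named", "organ_label")
  }
  unknown <- setdiff(names(organ_doses), names(weights))
  if (length(unknown) > 0) {
    peddose_abort(paste0("unknown organ label(s): ",
                         paste(unknown, collapse = ", ")), "organ_label")
  }
  if (any(is.na(organ_doses)) || any(organ_doses < 0)) {
    peddose_abort("organ doses must be non-negative", "domain")
  }
  sum(weights[names(organ_doses)] * organ_doses)
}

#' Per-scan conversion coefficient
#'
#' The scan-specific DLP-to-effective-dose coefficient, the ratio of the
#' reference (Monte-Carlo-style) effective dose to the scanner-reported DLP.
#'
#' @param e_reference Reference effective dose, mSv (non-negative).
#' @param dlp Dose length product, mGy·cm (strictly positive).
#' @return Coefficient in mSv per mGy·cm. Vectorized.
#' @export
scan_coefficient <- function(e_reference, dlp) {
  if (any(is.na(dlp)) || any(dlp <= 0)) {
    peddose_abort("dlp must be strictly positive", "domain")
  }
  if (any(is.na(e_reference)) || any(e_reference < 0)) {
    peddose_abort("e_reference must be non-negative", "domain")
  }
  e_reference / dlp
}

#' DLP-derived effective dose
#'
#' @param dlp Dose length product, mGy·cm (strictly positive).
#' @param k Conversion coefficient, mSv per mGy·cm (strictly positive).
#' @return Estimated effective dose in mSv. Vectorized.
#' @export
dlp_derived_dose <- function(dlp, k) {
  if (any(is.na(dlp)) || any(dlp <= 0) || any(is.na(k)) || any(k <= 0)) {
    peddose_abort("dlp and k must be strictly positive", "domain")
  }
  dlp * k
}

#' Assign age groups and diameter bins
#'
#' `assign_age_group()` bins ages (years) into the five half-open study
#' groups; every age in `[0, 22)` maps to exactly one group and boundary
#' ages go to the upper group (an exactly 1-year-old is in `1-4`).
#' `assign_diameter_bin()` bins mean effective diameters (cm) into half-open
#' 5-cm bins with integer edges; diameters below 11 cm or at/above 41 cm are
#' clamped to the nearest bin with a warning, since real registries contain
#' such scans. Both are vectorized and pass `NA` through.
#'
#' @param age Age in years, within `[0, 22)`.
#' @param diameter Mean effective diameter in cm, strictly positive.
#' @return Character vector of group / bin labels.
#' @export
assign_age_group <- function(age) {
  chk <- age[!is.na(age)]
  if (any(chk < 0 | chk >= 22)) {
    peddose_abort("age must lie in [0, 22)", "domain")
  }
  as.character(cut(age, breaks = age_breaks(), labels = age_group_levels(),
                   right = FALSE))
}

#' @rdname assign_age_group
#' @export
assign_diameter_bin <- function(diameter) {
  chk <- diameter[!is.na(diameter)]
  if (any(chk <= 0)) {
    peddose_abort("diameter must be strictly positive", "domain")
  }
  out_of_range <- sum(chk < 11 | chk >= 41)
  if (out_of_range > 0) {
    peddose_warn(paste0(out_of_range,
                        " diameter value(s) outside [11, 41) cm clamped to the nearest bin"),
                 "diameter_clamped")
  }
  d <- pmin(pmax(diameter, 11), 40.999)
  as.character(cut(d, breaks = diameter_breaks(),
                   labels = diameter_bin_levels(), right = FALSE))
}

strategy_axes <- function(strategy) {
  switch(strategy,
         age = "age_group",
         diameter = "diameter_bin",
         age_diameter = c("age_group", "diameter_bin"),
         manufacturer_age = c("manufacturer", "age_group"),
         peddose_abort(paste0("unknown strategy: ", strategy), "parameter"))
}

#' Look up a conversion coefficient for one scan
#'
#' Returns the median coefficient of the stratum selected by `strategy`.
#' Head and neck scans always use age-based strata; a diameter-containing
#' strategy falls back to age for these regions with a logged notice.
#'
#' @param table A `peddose_coef_table`.
#' @param region Body region (one of [body_regions()]).
#' @param age Age in years, if the strategy needs it.
#' @param diameter Mean effective diameter in cm, if the strategy needs it.
#' @param manufacturer Scanner manufacturer, if the strategy needs it.
#' @param strategy One of `"age"`, `"diameter"`, `"age_diameter"`,
#'   `"manufacturer_age"`.
#' @return The stratum median coefficient (mSv per mGy·cm).
#' @export
lookup_coefficient <- function(table, region, age = NULL, diameter = NULL,
                               manufacturer = NULL,
                               strategy = c("age", "diameter", "age_diameter",
                                            "manufacturer_age")) {
  strategy <- match.arg(strategy)
  if (!region %in% body_regions()) {
    peddose_abort(paste0("unknown body region: ", region), "parameter")
  }
  if (region %in% no_diameter_regions() &&
      "diameter_bin" %in% strategy_axes(strategy)) {
    rlang::inform(paste0(region, " scans use age-matched coefficients; ",
                         "falling back from strategy '", strategy, "' to 'age'"),
                  class = "peddose_notice_strategy_fallback")
    strategy <- "age"
  }
  axes <- strategy_axes(strategy)
  key <- list(body_region = region)
  if ("age_group" %in% axes) {
    if (is.null(age) || is.na(age)) {
      peddose_abort("age required for this strategy", "parameter")
    }
    key$age_group <- assign_age_group(age)
  }
  if ("diameter_bin" %in% axes) {
    if (is.null(diameter) || is.na(diameter)) {
      peddose_abort("diameter required for this strategy", "parameter")
    }
    key$diameter_bin <- assign_diameter_bin(diameter)
  }
  if ("manufacturer" %in% axes) {
    if (is.null(manufacturer)) {
      peddose_abort("manufacturer required for this strategy", "parameter")
    }
    key$manufacturer <- manufacturer
  }
  all_axes <- c("age_group", "diameter_bin", "manufacturer")
  sel <- table$body_region == key$body_region
  for (a in all_axes) {
    sel <- sel & if (a %in% names(key)) {
      !is.na(table[[a]]) & table[[a]] == key[[a]]
    } else {
      is.na(table[[a]])
    }
  }
  hit <- which(sel)
  if (length(hit) != 1) {
    peddose_abort(paste0("no coefficient for stratum: ",
                         paste(names(key), unlist(key), sep = "=",
                               collapse = ", ")),
                  "missing_stratum")
  }
  table$median_k[hit]
}

#' Estimate DLP-derived effective dose for a scan table
#'
#' Vectorized coefficient lookup and multiplication: each scan's DLP is
#' multiplied by the median coefficient of its stratum under `strategy`.
#' Head/neck scans are matched on age-only strata regardless of strategy.
#' Scans whose stratum is absent from `table` (suppressed by the minimum-n
#' rule, out-of-table region, or a missing required field) receive `NA`.
#'
#' @inheritParams lookup_coefficient
#' @param scans Tibble of scan records.
#' @return Numeric vector of estimated doses (mSv), aligned with `scans`.
#' @export
estimate_effective_dose <- function(scans, table,
                                    strategy = c("age", "diameter",
                                                 "age_diameter",
                                                 "manufacturer_age")) {
  strategy <- match.arg(strategy)
  n <- nrow(scans)
  est <- rep(NA_real_, n)
  all_axes <- c("age_group", "diameter_bin", "manufacturer")

  ok_age <- !is.na(scans$age) & scans$age >= 0 & scans$age < 22
  age_group <- rep(NA_character_, n)
  if (any(ok_age)) age_group[ok_age] <- assign_age_group(scans$age[ok_age])
  ok_d <- !is.na(scans$mean_effective_diameter) & scans$mean_effective_diameter > 0
  diameter_bin <- rep(NA_character_, n)
  if (any(ok_d)) {
    diameter_bin[ok_d] <- suppressWarnings(
      assign_diameter_bin(scans$mean_effective_diameter[ok_d]))
  }
  keys <- tibble::tibble(
    body_region = scans$body_region,
    age_group = age_group,
    diameter_bin = diameter_bin,
    manufacturer = scans$manufacturer
  )

  for (part in c("with_diameter", "age_only")) {
    hn <- scans$body_region %in% no_diameter_regions()
    rows <- if (part == "age_only") which(hn) else which(!hn)
    if (length(rows) == 0) next
    axes <- if (part == "age_only") "age_group" else strategy_axes(strategy)
    tab_sel <- rep(TRUE, nrow(table))
    for (a in all_axes) {
      tab_sel <- tab_sel & if (a %in% axes) !is.na(table[[a]]) else is.na(table[[a]])
    }
    tab <- table[tab_sel, , drop = FALSE]
    if (nrow(tab) == 0) next
    key_str <- function(df, rows) {
      s <- df$body_region[rows]
      for (a in axes) s <- paste(s, df[[a]][rows], sep = "|")
      s
    }
    m <- match(key_str(keys, rows), key_str(tab, seq_len(nrow(tab))))
    k <- tab$median_k[m]
    est[rows] <- scans$dlp[rows] * k
  }
  est[!is.na(scans$dlp) & scans$dlp <= 0] <- NA_real_
  est
}
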