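#' Canonical body regions
#'
#' The seven body regions used throughout the package. Sinus and face exams
#' belong to `head`, cervical spine to `neck`, and whole-spine exams to
#' `chest_abdomen_pelvis`; `spine` covers thoracic or lumbar spine exams.
#'
#' @return Character vector of region identifiers.
#' @export
body_regions <- function() {
  c("head", "neck", "chest", "cardiac",
    "abdomen_pelvis", "chest_abdomen_pelvis", "spine")
}

#' Age-group and diameter-bin level sets
#'
#' Age groups are half-open intervals in years: `[0,1)`, `[1,5)`, `[5,10)`,
#' `[10,15)`, `[15,22)`. Diameter bins are half-open 5-cm intervals with
#' integer edges from 11 to 41 cm.
#'
#' @return Character vector of ordered level labels.
#' @export
age_group_levels <- function() c("<1", "1-4", "5-9", "10-14", "15-21")

#' @rdname age_group_levels
#' @export
diameter_bin_levels <- function() {
  c("11-15", "16-20", "21-25", "26-30", "31-35", "36-40")
}

#' @rdname age_group_levels
#' @export
manufacturer_levels <- function() c("GE", "Siemens", "Philips", "Canon", "other")

age_breaks <- function() c(0, 1, 5, 10, 15, 22)
diameter_breaks <- function() c(11, 16, 21, 26, 31, 36, 41)

# Regions for which coefficients are never stratified by patient diameter:
# reference doses for these are age-matched only.
no_diameter_regions <- function() c("head", "neck")

peddose_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("peddose_error_", class), "peddose_error"), ...)
}

peddose_warn <- function(message, class, ...) {
  rlang::warn(message, class = c(paste0("peddose_warning_", class), "peddose_warning"), ...)
}

# Round half away from zero (commonly used for printed one-decimal ratios;
# base round() rounds half to even). The 1e-9 nudge absorbs binary
# representation error in ratios of decimal inputs, e.g. 0.085/0.020.
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- rlang::`%||%`
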