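#' Coefficient tables
#'
#' A coefficient table maps a stratum — body region, optionally crossed with
#' age group, patient-diameter bin and scanner manufacturer — to the median
#' and interquartile range of the DLP-to-effective-dose conversion
#' coefficient (mSv per mGy·cm), together with the number of scans the
#' stratum was estimated from. Absent stratification axes are `NA`.
#'
#' `as_coef_table()` validates a data frame and stamps the class;
#' `read_coefficient_table()` / `write_coefficient_table()` round-trip the
#' CSV serialization, in which an empty string denotes an absent axis.
#'
#' @param x Data frame with columns `body_region`, `age_group`,
#'   `diameter_bin`, `manufacturer`, `median_k`, `q25_k`, `q75_k`, `n`.
#' @return A tibble of class `peddose_coef_table`.
#' @export
as_coef_table <- function(x) {
  required <- c("body_region", "age_group", "diameter_bin", "manufacturer",
                "median_k", "q25_k", "q75_k", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    peddose_abort(
      paste0("coefficient table lacks column(s): ",
             paste(missing_cols, collapse = ", ")),
      "bad_coef_table")
  }
  x <- tibble::as_tibble(x)[required]
  bad_region <- setdiff(unique(x$body_region), body_regions())
  if (length(bad_region) > 0) {
    peddose_abort(paste0("unknown body region(s): ",
                         paste(bad_region, collapse = ", ")),
                  "bad_coef_table")
  }
  if (any(!is.na(x$median_k) & x$median_k <= 0)) {
    peddose_abort("coefficient medians must be strictly positive", "bad_coef_table")
  }
  ok_iqr <- is.na(x$q25_k) | is.na(x$q75_k) |
    (x$q25_k <= x$median_k & x$median_k <= x$q75_k)
  if (!all(ok_iqr)) {
    peddose_abort("q25_k <= median_k <= q75_k violated", "bad_coef_table")
  }
  hn <- x$body_region %in% no_diameter_regions() & !is.na(x$diameter_bin)
  if (any(hn)) {
    peddose_abort("head/neck strata must not carry a diameter bin", "bad_coef_table")
  }
  class(x) <- c("peddose_coef_table", class(x))
  x
}

#' @rdname as_coef_table
#' @param path File path of a coefficient-table CSV.
#' @export
read_coefficient_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    body_region = readr::col_character(),
    age_group = readr::col_character(),
    diameter_bin = readr::col_character(),
    manufacturer = readr::col_character(),
    median_k = readr::col_double(),
    q25_k = readr::col_double(),
    q75_k = readr::col_double(),
    n = readr::col_integer()
  ), na = c("", "NA"))
  as_coef_table(df)
}

#' @rdname as_coef_table
#' @param table A `peddose_coef_table`.
#' @export
write_coefficient_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @export
print.peddose_coef_table <- function(x, ...) {
  axes <- c("age_group", "diameter_bin", "manufacturer")
  used <- axes[vapply(axes, function(a) any(!is.na(x[[a]])), logical(1))]
  cat("<coefficient table: ", nrow(x), " strata; axes beyond region: ",
      if (length(used)) paste(used, collapse = " x ") else "none",
      ">\n", sep = "")
  NextMethod()
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "peddose")
  if (!nzchar(p)) {
    peddose_abort(paste0("packaged data file not found: ", file), "fixture_integrity")
  }
  p
}

#' Published coefficient tables and registry composition
#'
#' `published_k_by_age()` and `published_k_by_diameter()` return the
#' published median (25th, 75th percentile) effective dose coefficients by
#' body region crossed with age group and with patient-diameter bin,
#' respectively, in mSv per mGy·cm. Head and neck coefficients exist only by
#' age. The spine `<1` year stratum is absent (too few scans).
#' `registry_counts()` returns the published scan counts by body region
#' crossed with sex, age group and scanner manufacturer, from which the
#' synthetic generator's default sampling mixes are built.
#'
#' @return A `peddose_coef_table`, or for `registry_counts()` a tibble with
#'   columns `body_region`, `variable`, `level`, `count`.
#' @export
published_k_by_age <- function() {
  read_coefficient_table(extdata_path("k_by_age.csv"))
}

#' @rdname published_k_by_age
#' @export
published_k_by_diameter <- function() {
  read_coefficient_table(extdata_path("k_by_diameter.csv"))
}

#' @rdname published_k_by_age
#' @export
registry_counts <- function() {
  df <- readr::read_csv(extdata_path("registry_counts.csv"),
                        col_types = readr::cols(
                          body_region = readr::col_character(),
                          variable = readr::col_character(),
                          level = readr::col_character(),
                          count = readr::col_integer()))
  # integrity: per-region category counts must reconcile with region totals
  totals <- df[df$variable == "total", ]
  for (v in c("sex", "age_group", "manufacturer")) {
    sub <- df[df$variable == v, ]
    s <- tapply(sub$count, sub$body_region, sum)
    if (!all(s[totals$body_region] == totals$count)) {
      peddose_abort("registry count fixture does not reconcile", "fixture_integrity")
    }
  }
  df
}
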