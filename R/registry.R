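scan_fields <- function() {
  c("scan_id", "body_region", "age", "sex", "mean_effective_diameter",
    "dlp", "ctdi_vol", "scan_length", "kvp", "mas", "manufacturer",
    "reporting_phantom", "is_perfusion", "e_reference")
}

numeric_scan_fields <- function() {
  c("age", "mean_effective_diameter", "dlp", "ctdi_vol", "scan_length",
    "kvp", "mas", "e_reference")
}

#' Normalize free-text body-region labels
#'
#' Maps common registry spellings onto the seven canonical regions: sinus and
#' face exams to `head`, cervical spine to `neck`, whole spine to
#' `chest_abdomen_pelvis`, thoracic/lumbar spine to `spine`. Unrecognized
#' labels become `NA` (and are later excluded as missing).
#'
#' @param x Character vector of region labels.
#' @return Character vector over [body_regions()] with `NA` for unknowns.
#' @export
normalize_body_region <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[^a-z0-9]+", "_", key)
  key <- gsub("^_|_$", "", key)
  map <- c(
    head = "head", sinus = "head", face = "head",
    neck = "neck", cervical_spine = "neck", c_spine = "neck",
    chest = "chest", thorax = "chest",
    cardiac = "cardiac", heart = "cardiac",
    abdomen_pelvis = "abdomen_pelvis", abdomen_and_pelvis = "abdomen_pelvis",
    abdomenpelvis = "abdomen_pelvis", abdomen = "abdomen_pelvis",
    pelvis = "abdomen_pelvis",
    chest_abdomen_pelvis = "chest_abdomen_pelvis",
    chest_abdomen_and_pelvis = "chest_abdomen_pelvis",
    combined_chest_abdomen_pelvis = "chest_abdomen_pelvis",
    combined_chest_abdomen_and_pelvis = "chest_abdomen_pelvis",
    cap = "chest_abdomen_pelvis", whole_spine = "chest_abdomen_pelvis",
    spine = "spine", thoracic_spine = "spine", lumbar_spine = "spine",
    thoracic_or_lumbar_spine = "spine", t_spine = "spine", l_spine = "spine"
  )
  unname(map[key])
}

#' Read a delimited table of CT scan records
#'
#' Reads a comma- or tab-separated file with a header row into the canonical
#' scan-record layout. `column_map` renames source columns to canonical field
#' names; it may be a named character vector (`canonical = "source name"`) or
#' the path of a YAML file holding one. Unmapped canonical fields that are
#' absent from the source are filled with `NA`. Numeric fields that fail to
#' parse become `NA`, never zero. Row order is preserved.
#'
#' @param path Path to the delimited file.
#' @param column_map Optional named character vector or YAML file path.
#' @param delim Field delimiter; guessed from the header line when `NULL`.
#' @return A tibble with one row per scan and the columns of `scan_fields()`.
#' @export
read_scan_table <- function(path, column_map = NULL, delim = NULL) {
  if (is.character(column_map) && length(column_map) == 1 &&
      is.null(names(column_map)) && file.exists(column_map)) {
    column_map <- unlist(yaml::read_yaml(column_map))
  }
  if (!file.exists(path)) {
    peddose_abort(paste0("scan table not found: ", path), "io")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    peddose_abort(paste0("scan table is empty: ", path), "empty_input")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"),
    show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    peddose_abort(paste0("scan table has a header but no rows: ", path),
                  "empty_input")
  }
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(raw)) {
        peddose_abort(paste0("mapped column not in file: ", src), "config")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  mandatory <- c("body_region", "age", "dlp")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) {
    peddose_abort(paste0("mandatory column(s) missing: ",
                         paste(absent, collapse = ", ")), "config")
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (f in scan_fields()) {
    out[[f]] <- if (f %in% names(raw)) raw[[f]] else NA_character_
  }
  for (f in numeric_scan_fields()) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  if (all(is.na(out$scan_id))) out$scan_id <- sprintf("row%06d", seq_len(nrow(out)))
  out$body_region <- normalize_body_region(out$body_region)
  out$sex <- ifelse(toupper(substr(out$sex, 1, 1)) %in% c("F", "M"),
                    toupper(substr(out$sex, 1, 1)), "unknown")
  mf <- trimws(out$manufacturer)
  canon <- manufacturer_levels()
  idx <- match(tolower(mf), tolower(canon))
  idx[tolower(mf) %in% c("general electric", "ge healthcare")] <- 1L
  idx[tolower(mf) %in% c("toshiba", "canon medical")] <- 4L
  out$manufacturer <- ifelse(is.na(mf), "other",
                             ifelse(is.na(idx), "other", canon[idx]))
  ph <- gsub("[^0-9]", "", out$reporting_phantom %||% NA_character_)
  out$reporting_phantom <- ifelse(ph %in% c("16", "32"),
                                  paste0(ph, "cm"), "unknown")
  out$is_perfusion <- tolower(trimws(out$is_perfusion)) %in%
    c("true", "t", "1", "yes", "y")
  out
}

new_exclusion_log <- function(input_n, retained_n, counts) {
  structure(list(input_n = as.integer(input_n),
                 retained_n = as.integer(retained_n),
                 counts = counts),
            class = "peddose_exclusion_log")
}

#' @export
print.peddose_exclusion_log <- function(x, ...) {
  cat("Exclusion log: ", x$input_n, " in, ", x$retained_n, " retained\n", sep = "")
  for (nm in names(x$counts)) {
    if (x$counts[[nm]] > 0) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Apply registry inclusion/exclusion filters
#'
#' Removes, in order: (1) perfusion scans; (2) records with missing or
#' erroneous core data — missing body region, age or DLP, non-positive DLP,
#' CTDI-vol, diameter or scan length, or age outside `[0, 22)`; (3) records
#' whose value on any trim variable falls strictly below the
#' `trim_fraction` quantile or strictly above the `1 - trim_fraction`
#' quantile of that variable. Trim quantiles are computed on the set
#' surviving step 2 (jointly over all trim variables, each record counted
#' once under the first variable that flags it); records missing an optional
#' trim variable are not trimmed on it, and boundary-equal values are
#' retained.
#'
#' @param scans Tibble of scan records (see [read_scan_table()]).
#' @param trim_fraction Proportion trimmed per tail, in `[0, 0.5)`.
#'   Default 0.01 (bottom and top one percent).
#' @param trim_variables Variables subject to tail trimming.
#' @param per_region Compute trim quantiles within each body region rather
#'   than globally. Default `FALSE` (global quantiles).
#' @return List with `scans` (the retained records) and `log`, an exclusion
#'   log whose counts reconcile exactly with `nrow(input) - nrow(output)`.
#' @export
apply_exclusions <- function(scans,
                             trim_fraction = 0.01,
                             trim_variables = c("ctdi_vol", "dlp",
                                                "mean_effective_diameter",
                                                "scan_length", "e_reference",
                                                "mas"),
                             per_region = FALSE) {
  if (!is.numeric(trim_fraction) || length(trim_fraction) != 1 ||
      is.na(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5) {
    peddose_abort("trim_fraction must lie in [0, 0.5)", "parameter")
  }
  input_n <- nrow(scans)
  counts <- integer(0)

  perf <- !is.na(scans$is_perfusion) & scans$is_perfusion
  counts["perfusion"] <- sum(perf)
  scans <- scans[!perf, , drop = FALSE]

  bad <- is.na(scans$body_region) | is.na(scans$age) | is.na(scans$dlp) |
    scans$dlp <= 0 | scans$age < 0 | scans$age >= 22 |
    (!is.na(scans$ctdi_vol) & scans$ctdi_vol <= 0) |
    (!is.na(scans$mean_effective_diameter) & scans$mean_effective_diameter <= 0) |
    (!is.na(scans$scan_length) & scans$scan_length <= 0)
  counts["missing_fields"] <- sum(bad)
  scans <- scans[!bad, , drop = FALSE]

  trimmed_by <- rep(NA_character_, nrow(scans))
  if (trim_fraction > 0 && nrow(scans) > 0) {
    for (v in trim_variables) {
      if (!v %in% names(scans)) next
      x <- scans[[v]]
      grp <- if (per_region) scans$body_region else rep("all", length(x))
      flag <- rep(FALSE, length(x))
      for (g in unique(grp)) {
        i <- which(grp == g & !is.na(x))
        if (length(i) == 0) next
        q <- quantile(x[i], c(trim_fraction, 1 - trim_fraction),
                      type = 7, names = FALSE)
        flag[i] <- x[i] < q[1] | x[i] > q[2]
      }
      hit <- flag & is.na(trimmed_by)
      trimmed_by[hit] <- v
    }
  }
  for (v in trim_variables) {
    counts[paste0("tail_trim:", v)] <- sum(trimmed_by == v, na.rm = TRUE)
  }
  scans <- scans[is.na(trimmed_by), , drop = FALSE]

  log <- new_exclusion_log(input_n, nrow(scans), as.list(counts))
  stopifnot(log$retained_n + sum(unlist(log$counts)) == log$input_n)
  list(scans = scans, log = log)
}

#' Subsample scans within an age band
#'
#' Retains each scan inside `band` independently with probability `fraction`
#' under a seeded generator; scans outside the band are always retained.
#' Mirrors registry assembly designs that down-sample the oldest patients
#' (e.g. a 5% sample of 18–21-year-olds) so they do not dominate results.
#' Deterministic for a fixed seed.
#'
#' @param scans Tibble of scan records.
#' @param band Half-open age interval `[lo, hi)` in years. Default `c(18, 22)`.
#' @param fraction Retention probability in `(0, 1]`. Default 0.05.
#' @param seed Integer seed.
#' @return The subsampled tibble; the number of removed records is available
#'   as `attr(, "n_removed")`.
#' @export
subsample_age_band <- function(scans, band = c(18, 22), fraction = 0.05,
                               seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    peddose_abort("fraction must lie in (0, 1]", "parameter")
  }
  if (fraction == 1) {
    attr(scans, "n_removed") <- 0L
    return(scans)
  }
  in_band <- !is.na(scans$age) & scans$age >= band[1] & scans$age < band[2]
  keep <- rep(TRUE, nrow(scans))
  if (any(in_band)) {
    u <- withr::with_seed(seed, runif(sum(in_band)))
    keep[in_band] <- u < fraction
  }
  out <- scans[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
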