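# Build a minimal scan tibble with recycled defaults; any field overridable.
make_scans <- function(n = 10, body_region = "chest", age = 8, dlp = 100,
                       e_reference = NA_real_,
                       mean_effective_diameter = NA_real_,
                       ctdi_vol = NA_real_, scan_length = NA_real_,
                       mas = NA_real_, kvp = NA_real_,
                       sex = "unknown", manufacturer = "other",
                       reporting_phantom = "unknown",
                       is_perfusion = FALSE) {
  tibble::tibble(
    scan_id = sprintf("T%04d", seq_len(n)),
    body_region = rep_len(body_region, n),
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    mean_effective_diameter = rep_len(mean_effective_diameter, n),
    dlp = rep_len(dlp, n),
    ctdi_vol = rep_len(ctdi_vol, n),
    scan_length = rep_len(scan_length, n),
    kvp = rep_len(kvp, n),
    mas = rep_len(mas, n),
    manufacturer = rep_len(manufacturer, n),
    reporting_phantom = rep_len(reporting_phantom, n),
    is_perfusion = rep_len(is_perfusion, n),
    e_reference = rep_len(e_reference, n))
}

# Brute-force type-7 percentile (linear interpolation between order
# statistics), kept independent of stats::quantile for oracle use.
bf_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
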