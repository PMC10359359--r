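age_group_interval <- function(group) {
  b <- age_breaks()
  i <- match(group, age_group_levels())
  cbind(lo = b[i], hi = b[i + 1])
}

default_dlp_params <- function() {
  tibble::tibble(
    body_region = body_regions(),
    dlp0 = c(400, 150, 60, 80, 80, 120, 100),   # median DLP at age 0, mGy·cm
    dlp_slope = c(0.015, 0.08, 0.12, 0.10, 0.15, 0.12, 0.10),  # per year
    sdlog = c(0.45, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
}

default_scan_length_params <- function() {
  tibble::tibble(
    body_region = body_regions(),
    len0 = c(20, 18, 28, 14, 40, 60, 35),  # median scan length at age 21, cm
    sdlog = rep(0.15, 7))
}

mix_from_counts <- function(counts, variable) {
  sub <- counts[counts$variable == variable, ]
  split_levels <- split(sub, sub$body_region)
  lapply(split_levels, function(d) setNames(d$count / sum(d$count), d$level))
}

#' Synthetic registry configuration
#'
#' Builds the parameter set for [generate_registry()]. Defaults emulate the
#' published registry composition: the region mix and region-conditional
#' age, sex and manufacturer mixes are the empirical proportions from
#' [registry_counts()], and the true conversion coefficients are the
#' published age-stratified medians ([published_k_by_age()]). Patient
#' diameter follows a log-normal model whose median grows linearly with age
#' (`d0 + d1 * age` cm); DLP and scan length follow region-specific
#' log-normal models. The reference dose is `k_true * dlp` perturbed by
#' multiplicative log-normal noise: `noise_sigma` defaults to the value
#' implied by the published coefficient IQR ratios (the median over strata
#' of `log(q75/q25) / (2 * qnorm(0.75))`, about 0.41), so that the
#' simulated per-scan coefficient spread matches the published spread.
#'
#' @param n_scans Number of scans to generate.
#' @param seed Integer seed; the whole registry is a deterministic function
#'   of the configuration.
#' @param k_true True coefficient table (region by age group).
#' @param diameter_effect If `TRUE`, modulate `k_true` multiplicatively by
#'   the published diameter-stratum medians (normalized per region to
#'   geometric mean 1), making the true coefficient diameter-dependent.
#' @param noise_sigma Log-scale dispersion of the multiplicative dose error.
#' @param region_mix,age_mix,sex_mix,manufacturer_mix Optional overrides:
#'   `region_mix` a named probability vector; the others named lists of
#'   per-region probability vectors.
#' @param diameter_params List with `d0` (cm), `d1` (cm/year), `sigma_d`
#'   (log-scale SD). Defaults 11, 0.8, 0.12.
#' @param dlp_params,scan_length_params Per-region log-normal parameter
#'   tables; see defaults in the package vignette.
#' @param perfusion_rate,missing_dlp_rate,missing_age_rate,missing_diameter_rate
#'   Small proportions for exercising the exclusion filters.
#' @param headneck_diameter_missing Probability that a head/neck scan lacks
#'   a recorded diameter (default 1: never recorded).
#' @return A list of class `peddose_sim_config`.
#' @export
synthetic_config <- function(n_scans = 10000L, seed = 1L,
                             k_true = NULL, diameter_effect = FALSE,
                             noise_sigma = NULL,
                             region_mix = NULL, age_mix = NULL,
                             sex_mix = NULL, manufacturer_mix = NULL,
                             diameter_params = list(d0 = 11, d1 = 0.8,
                                                    sigma_d = 0.12),
                             dlp_params = default_dlp_params(),
                             scan_length_params = default_scan_length_params(),
                             perfusion_rate = 0.005,
                             missing_dlp_rate = 0.003,
                             missing_age_rate = 0.002,
                             missing_diameter_rate = 0.01,
                             headneck_diameter_missing = 1.0) {
  if (!is.numeric(n_scans) || n_scans < 1) {
    peddose_abort("n_scans must be >= 1", "parameter")
  }
  counts <- registry_counts()
  if (is.null(region_mix)) {
    tot <- counts[counts$variable == "total", ]
    region_mix <- setNames(tot$count / sum(tot$count), tot$body_region)
  }
  age_mix <- age_mix %||% mix_from_counts(counts, "age_group")
  sex_mix <- sex_mix %||% mix_from_counts(counts, "sex")
  manufacturer_mix <- manufacturer_mix %||% mix_from_counts(counts, "manufacturer")
  k_true <- k_true %||% published_k_by_age()

  if (is.null(noise_sigma)) {
    ok <- !is.na(k_true$q25_k) & !is.na(k_true$q75_k) & k_true$q25_k > 0
    ratio <- k_true$q75_k[ok] / k_true$q25_k[ok]
    noise_sigma <- stats::median(log(ratio)) / (2 * qnorm(0.75))
  }
  if (noise_sigma < 0) peddose_abort("noise_sigma must be >= 0", "parameter")

  check_mix <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      peddose_abort(paste0(what, " probabilities must be >= 0 and sum to 1"),
                    "parameter")
    }
  }
  check_mix(region_mix, "region_mix")
  for (r in names(age_mix)) check_mix(age_mix[[r]], paste0("age_mix[", r, "]"))
  for (r in names(sex_mix)) check_mix(sex_mix[[r]], paste0("sex_mix[", r, "]"))
  for (r in names(manufacturer_mix)) {
    check_mix(manufacturer_mix[[r]], paste0("manufacturer_mix[", r, "]"))
  }
  rates <- c(perfusion_rate, missing_dlp_rate, missing_age_rate,
             missing_diameter_rate, headneck_diameter_missing)
  if (any(rates < 0 | rates > 1)) {
    peddose_abort("rates must lie in [0, 1]", "parameter")
  }

  structure(list(
    n_scans = as.integer(n_scans), seed = as.integer(seed),
    region_mix = region_mix, age_mix = age_mix, sex_mix = sex_mix,
    manufacturer_mix = manufacturer_mix,
    k_true = k_true, diameter_effect = diameter_effect,
    noise_sigma = noise_sigma,
    diameter_params = diameter_params,
    dlp_params = dlp_params, scan_length_params = scan_length_params,
    perfusion_rate = perfusion_rate,
    missing_dlp_rate = missing_dlp_rate,
    missing_age_rate = missing_age_rate,
    missing_diameter_rate = missing_diameter_rate,
    headneck_diameter_missing = headneck_diameter_missing),
    class = "peddose_sim_config")
}

#' @export
print.peddose_sim_config <- function(x, ...) {
  cat("<synthetic registry config: n =", x$n_scans, ", seed =", x$seed,
      ", noise_sigma =", signif(x$noise_sigma, 3),
      ", diameter_effect =", x$diameter_effect, ">\n")
  invisible(x)
}

# Per-region diameter modulation factors: published diameter medians
# normalized to geometric mean 1 within each region.
diameter_modulation <- function() {
  kd <- published_k_by_diameter()
  out <- list()
  for (r in unique(kd$body_region)) {
    rows <- kd[kd$body_region == r, ]
    f <- rows$median_k / exp(mean(log(rows$median_k)))
    out[[r]] <- setNames(f, rows$diameter_bin)
  }
  out
}

#' Generate a synthetic scan registry
#'
#' Draws `n_scans` scan records emulating the statistical structure of a
#' pediatric CT dose registry: body region, age group (restricted to strata
#' present in the true coefficient table, so e.g. spine `<1` is never
#' sampled), uniform age within group, sex and manufacturer from the
#' region-conditional mixes, a log-normal age-dependent diameter, log-normal
#' region- and age-dependent DLP and scan length (with
#' `ctdi_vol = dlp / scan_length`), and a reference effective dose
#' `e_reference = k_true * dlp * exp(noise_sigma * Z)` with standard normal
#' `Z`. Perfusion flags and missing values are injected at the configured
#' rates so exclusion filters can be exercised. Bit-identical for a fixed
#' configuration (the seed lives in the config).
#'
#' @param config A `peddose_sim_config`.
#' @param per_stratum_n If supplied, ignore the region/age mixes and instead
#'   generate exactly this many scans for every region-by-age stratum of the
#'   true coefficient table (balanced design for recovery studies).
#' @return Tibble of scan records (see [read_scan_table()] for the layout)
#'   with `e_reference` and `is_perfusion` populated.
#' @export
generate_registry <- function(config, per_stratum_n = NULL) {
  stopifnot(inherits(config, "peddose_sim_config"))
  kt <- config$k_true
  strata <- kt[!is.na(kt$age_group) & is.na(kt$diameter_bin) &
                 is.na(kt$manufacturer), , drop = FALSE]

  withr::with_seed(config$seed, {
    if (!is.null(per_stratum_n)) {
      region <- rep(strata$body_region, each = per_stratum_n)
      age_group <- rep(strata$age_group, each = per_stratum_n)
      n <- length(region)
    } else {
      n <- config$n_scans
      region <- sample(names(config$region_mix), n, replace = TRUE,
                       prob = config$region_mix)
      age_group <- character(n)
      for (r in body_regions()) {
        i <- which(region == r)
        if (length(i) == 0) next
        mix <- config$age_mix[[r]]
        avail <- strata$age_group[strata$body_region == r]
        mix <- mix[names(mix) %in% avail]
        mix <- mix / sum(mix)
        age_group[i] <- sample(names(mix), length(i), replace = TRUE, prob = mix)
      }
    }

    iv <- age_group_interval(age_group)
    age <- runif(n, iv[, "lo"], iv[, "hi"])

    sex <- character(n); manufacturer <- character(n)
    for (r in body_regions()) {
      i <- which(region == r)
      if (length(i) == 0) next
      sex[i] <- sample(names(config$sex_mix[[r]]), length(i), replace = TRUE,
                       prob = config$sex_mix[[r]])
      manufacturer[i] <- sample(names(config$manufacturer_mix[[r]]), length(i),
                                replace = TRUE,
                                prob = config$manufacturer_mix[[r]])
    }

    dp <- config$diameter_params
    diameter <- (dp$d0 + dp$d1 * age) * exp(dp$sigma_d * rnorm(n))
    p_miss_d <- ifelse(region %in% no_diameter_regions(),
                       config$headneck_diameter_missing,
                       config$missing_diameter_rate)
    diameter[runif(n) < p_miss_d] <- NA_real_

    dlp_p <- config$dlp_params[match(region, config$dlp_params$body_region), ]
    dlp <- dlp_p$dlp0 * (1 + dlp_p$dlp_slope * age) *
      exp(dlp_p$sdlog * rnorm(n))
    len_p <- config$scan_length_params[
      match(region, config$scan_length_params$body_region), ]
    scan_length <- len_p$len0 * (0.5 + 0.5 * age / 21) *
      exp(len_p$sdlog * rnorm(n))
    ctdi_vol <- dlp / scan_length
    kvp <- sample(c(80, 100, 120), n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
    mas <- 100 * exp(0.4 * rnorm(n))

    m <- match(paste(region, age_group), paste(strata$body_region,
                                               strata$age_group))
    k <- strata$median_k[m]
    if (isTRUE(config$diameter_effect)) {
      mod <- diameter_modulation()
      bin <- rep(NA_character_, n)
      ok <- !is.na(diameter)
      if (any(ok)) bin[ok] <- suppressWarnings(assign_diameter_bin(diameter[ok]))
      for (r in names(mod)) {
        i <- which(region == r & !is.na(bin))
        if (length(i) == 0) next
        f <- mod[[r]][bin[i]]
        f[is.na(f)] <- 1  # bins outside the published range are unmodulated
        k[i] <- k[i] * f
      }
    }
    e_reference <- k * dlp * exp(config$noise_sigma * rnorm(n))

    is_perfusion <- runif(n) < config$perfusion_rate
    dlp[runif(n) < config$missing_dlp_rate] <- NA_real_
    age[runif(n) < config$missing_age_rate] <- NA_real_
    reporting_phantom <- ifelse(
      region == "head",
      ifelse(runif(n) < 0.99, "16cm", "32cm"),
      ifelse(runif(n) < 0.95, "32cm", "16cm"))

    tibble::tibble(
      scan_id = sprintf("S%07d", seq_len(n)),
      body_region = region, age = age, sex = sex,
      mean_effective_diameter = diameter,
      dlp = dlp, ctdi_vol = ctdi_vol, scan_length = scan_length,
      kvp = kvp, mas = mas, manufacturer = manufacturer,
      reporting_phantom = reporting_phantom,
      is_perfusion = is_perfusion, e_reference = e_reference)
  })
}
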