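test_that("Pearson correlation matches a direct formula evaluation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  res <- pearson_with_ci(x, y)
  # frozen from the direct sum formula on these ten numbers
  expect_equal(res$r, 0.821994936526786, tolerance = 1e-12)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)

  expect_equal(pearson_with_ci(x, x)$r, 1.0)
  expect_equal(pearson_with_ci(x, -x)$r, -1.0)
})

test_that("Fisher-z interval agrees with the standard implementation", {
  withr::with_seed(9, {
    x <- rnorm(60)
    y <- 0.6 * x + rnorm(60, sd = 0.8)
  })
  res <- pearson_with_ci(x, y)
  ref <- cor.test(x, y)  # independent oracle
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_with_ci(c(1, 1, 1), c(1, 2, 3)),
               class = "peddose_error_degenerate_input")
  expect_error(pearson_with_ci(c(1, 2), c(1, 2)),
               class = "peddose_error_insufficient_data")
  expect_error(pearson_with_ci(c(1, 2, NA), c(1, 2, 3)),
               class = "peddose_error_domain")
})

test_that("CI width shrinks with n on nested samples", {
  withr::with_seed(12, {
    x <- rnorm(800)
    y <- 0.7 * x + rnorm(800, sd = 0.7)
  })
  widths <- sapply(c(50, 200, 800), function(n) {
    res <- pearson_with_ci(x[1:n], y[1:n])
    res$ci_high - res$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("relative-error percentage follows the >= threshold convention", {
  expect_equal(pct_relative_error_above(c(1, 2, 3), c(1, 2, 3))$pct, 0)
  expect_equal(pct_relative_error_above(1.6 * c(1, 2, 3), c(1, 2, 3))$pct, 100)
  # errors 0.2, 0.6, 0.6, 0.5; >= includes the boundary case
  res <- pct_relative_error_above(c(1.2, 1.6, 0.4, 1.5), rep(1, 4))
  expect_equal(res$pct, 75)
  expect_equal(pct_relative_error_above(c(1.2, 1.6, 0.4, 1.5), rep(1, 4),
                                        strict = TRUE)$pct, 50)
  expect_error(pct_relative_error_above(c(1, 1), c(1, 0)),
               class = "peddose_error_domain")
})

test_that("relative-error percentage is invariant to common rescaling", {
  withr::with_seed(14, {
    ref <- runif(200, 1, 20)
    est <- ref * exp(rnorm(200, sd = 0.4))
  })
  a <- pct_relative_error_above(est, ref)
  b <- pct_relative_error_above(7.3 * est, 7.3 * ref)
  expect_equal(a$pct, b$pct)
})

test_that("missing estimates are excluded and counted separately", {
  res <- pct_relative_error_above(c(NA, 1.6, 1.0), c(1, 1, 1))
  expect_equal(res$n, 2)
  expect_equal(res$n_missing, 1)
  expect_equal(res$pct, 50)
})

test_that("legacy coefficients apply through the reference-age mapping", {
  legacy <- tibble::tibble(
    body_region = rep("chest", 5),
    age_label = names(legacy_age_map()),
    k = c(0.1, 0.08, 0.06, 0.04, 0.02))
  scans <- make_scans(3, body_region = "chest", age = c(3, 0.5, 20),
                      dlp = c(200, 100, 400))
  doses <- apply_legacy_coefficients(scans, legacy)
  expect_equal(doses, c(200 * 0.08, 100 * 0.1, 400 * 0.02))

  # unmapped region is an error
  other <- make_scans(1, body_region = "head", age = 3)
  expect_error(apply_legacy_coefficients(other, legacy),
               class = "peddose_error_missing_mapping")
})

test_that("a legacy set equal to the study table reproduces its doses", {
  ka <- published_k_by_age()
  chest <- ka[ka$body_region == "chest", ]
  legacy <- tibble::tibble(
    body_region = "chest",
    age_label = names(legacy_age_map())[match(chest$age_group,
                                              legacy_age_map())],
    k = chest$median_k)
  scans <- make_scans(5, body_region = "chest", age = c(0.5, 3, 7, 12, 18),
                      dlp = 100)
  expect_equal(apply_legacy_coefficients(scans, legacy),
               estimate_effective_dose(scans, ka, "age"))
})

test_that("noiseless self-estimation is perfect in every region", {
  cfg <- synthetic_config(n_scans = 6000, seed = 17, noise_sigma = 0)
  reg <- generate_registry(cfg)
  report <- agreement_report(reg, list(age = cfg$k_true))
  expect_setequal(unique(report$body_region), body_regions())
  expect_true(all(abs(report$pearson_r - 1) < 1e-12))
  expect_true(all(report$pct_gt_threshold == 0))
})

test_that("added noise monotonically degrades agreement on a fixed seed", {
  sigma <- synthetic_config(n_scans = 1, seed = 1)$noise_sigma
  run <- function(s) {
    cfg <- synthetic_config(n_scans = 8000, seed = 19, noise_sigma = s)
    reg <- generate_registry(cfg)
    agreement_report(reg, list(age = cfg$k_true))
  }
  r1 <- run(sigma)
  r2 <- run(2 * sigma)
  m <- match(r1$body_region, r2$body_region)
  expect_true(all(r2$pearson_r[m] < r1$pearson_r))
  expect_true(all(r2$pct_gt_threshold[m] > r1$pct_gt_threshold))
  # and it sits strictly inside the bounds at the default level
  expect_true(all(r1$pearson_r > 0 & r1$pearson_r < 1))
  expect_true(all(r1$pct_gt_threshold > 0 & r1$pct_gt_threshold < 100))
})

test_that("age-diameter strata do not underperform age strata when the true
           coefficient is diameter-dependent", {
  cfg <- synthetic_config(seed = 23, diameter_effect = TRUE,
                          missing_diameter_rate = 0)
  reg <- generate_registry(cfg, per_stratum_n = 800)
  t_age <- derive_coefficients(reg, axes = "age_group")
  t_ad <- derive_coefficients(reg, axes = c("age_group", "diameter_bin"))
  report <- agreement_report(reg, list(age = t_age, age_diameter = t_ad))
  wide <- split(report, report$body_region)
  for (reg_name in names(wide)) {
    rows <- wide[[reg_name]]
    if (!all(c("age", "age_diameter") %in% rows$strategy)) next
    r_age <- rows$pearson_r[rows$strategy == "age"]
    r_ad <- rows$pearson_r[rows$strategy == "age_diameter"]
    expect_gte(r_ad, r_age - 1e-10)
  }
})

test_that("agreement reports follow the region-by-strategy layout", {
  cfg <- synthetic_config(n_scans = 8000, seed = 29)
  reg <- generate_registry(cfg)
  t_age <- derive_coefficients(reg, axes = "age_group")
  t_diam <- derive_coefficients(reg, axes = "diameter_bin")
  report <- agreement_report(reg, list(age = t_age, diameter = t_diam))
  expect_named(report, c("body_region", "strategy", "n", "n_unmatched",
                         "pearson_r", "ci_low", "ci_high",
                         "pct_gt_threshold", "threshold"))
  # head and neck appear for age but never for diameter strategies
  diam_rows <- report[report$strategy == "diameter", ]
  expect_false(any(diam_rows$body_region %in% c("head", "neck")))
  age_rows <- report[report$strategy == "age", ]
  expect_true(all(c("head", "neck") %in% age_rows$body_region))
  expect_true(all(report$ci_low <= report$pearson_r &
                    report$pearson_r <= report$ci_high))
  expect_true(all(report$pct_gt_threshold >= 0 &
                    report$pct_gt_threshold <= 100))
})
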