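test_that("constant-ratio scans give a degenerate stratum summary", {
  scans <- make_scans(50, body_region = "chest", age = 7, dlp = seq(200, 249),
                      e_reference = 0.05 * seq(200, 249))
  tab <- derive_coefficients(scans, axes = "age_group")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$median_k, 0.05, tolerance = 1e-12)
  expect_equal(tab$q25_k, 0.05, tolerance = 1e-12)
  expect_equal(tab$q75_k, 0.05, tolerance = 1e-12)
  expect_equal(tab$n, 50)
})

test_that("strata below min_n are omitted, never zero-filled", {
  scans <- rbind(
    make_scans(9, body_region = "chest", age = 2, dlp = 100,
               e_reference = 10),
    make_scans(12, body_region = "chest", age = 7, dlp = 100,
               e_reference = 8))
  tab <- derive_coefficients(scans, axes = "age_group", min_n = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$age_group, "5-9")
  # lowering min_n restores the small stratum
  tab2 <- derive_coefficients(scans, axes = "age_group", min_n = 5)
  expect_equal(nrow(tab2), 2)
})

test_that("stratum percentiles match a brute-force order-statistic oracle", {
  k <- seq(0.01, 0.11, by = 0.01)
  scans <- make_scans(11, body_region = "neck", age = 3, dlp = 1000,
                      e_reference = 1000 * k)
  tab <- derive_coefficients(scans, axes = "age_group", min_n = 10)
  expect_equal(tab$median_k, bf_percentile(k, 0.5), tolerance = 1e-12)
  expect_equal(tab$q25_k, bf_percentile(k, 0.25), tolerance = 1e-12)
  expect_equal(tab$q75_k, bf_percentile(k, 0.75), tolerance = 1e-12)
  # frozen values from the oracle: 0.060, 0.035, 0.085
  expect_equal(tab$median_k, 0.060)
  expect_equal(tab$q25_k, 0.035)
  expect_equal(tab$q75_k, 0.085)
})

test_that("derivation is scale-equivariant and permutation-invariant", {
  cfg <- synthetic_config(n_scans = 2000, seed = 21)
  reg <- generate_registry(cfg)
  reg <- reg[!is.na(reg$dlp) & !is.na(reg$age), ]
  t1 <- derive_coefficients(reg, axes = "age_group")
  scaled <- reg
  scaled$e_reference <- scaled$e_reference * 3
  t2 <- derive_coefficients(scaled, axes = "age_group")
  expect_equal(t2$median_k, 3 * t1$median_k, tolerance = 1e-12)
  expect_equal(t2$q25_k, 3 * t1$q25_k, tolerance = 1e-12)
  shuffled <- reg[withr::with_seed(1, sample(nrow(reg))), ]
  t3 <- derive_coefficients(shuffled, axes = "age_group")
  expect_equal(t3, t1, ignore_attr = TRUE)
})

test_that("head and neck are never stratified by diameter", {
  cfg <- synthetic_config(n_scans = 4000, seed = 8,
                          headneck_diameter_missing = 0.5)
  reg <- generate_registry(cfg)
  tab <- derive_coefficients(reg, axes = "diameter_bin")
  expect_false(any(tab$body_region %in% c("head", "neck")))
  tab2 <- derive_coefficients(reg, axes = c("age_group", "diameter_bin"))
  hn <- tab2[tab2$body_region %in% c("head", "neck"), ]
  expect_true(all(is.na(hn$diameter_bin)))
  expect_gt(nrow(hn), 0)
})

test_that("published relative coefficients reproduce from the packaged tables", {
  ka <- published_k_by_age()
  age_expected <- c(head = 13.0, neck = 6.9, chest = 6.8, cardiac = 4.0,
                    abdomen_pelvis = 3.7, chest_abdomen_pelvis = 5.1,
                    spine = 2.7)
  for (r in names(age_expected)) {
    expect_equal(relative_coefficient(ka, r, "age_group")$value,
                 unname(age_expected[r]), info = r)
  }
  kd <- published_k_by_diameter()
  diam_expected <- c(chest = 5.3, cardiac = 5.5, abdomen_pelvis = 5.1,
                     chest_abdomen_pelvis = 4.3, spine = 1.3)
  for (r in names(diam_expected)) {
    expect_equal(relative_coefficient(kd, r, "diameter_bin")$value,
                 unname(diam_expected[r]), info = r)
  }
})

test_that("spine age ratio uses 1-4 as youngest available group", {
  rc <- relative_coefficient(published_k_by_age(), "spine", "age_group")
  expect_equal(rc$numerator_stratum, "1-4")
  expect_equal(rc$denominator_stratum, "15-21")
})

test_that("equal extreme medians give a relative coefficient of 1.0", {
  tab <- as_coef_table(tibble::tibble(
    body_region = "chest", age_group = c("<1", "15-21"),
    diameter_bin = NA_character_, manufacturer = NA_character_,
    median_k = c(0.05, 0.05), q25_k = c(0.04, 0.04),
    q75_k = c(0.06, 0.06), n = c(20L, 20L)))
  expect_equal(relative_coefficient(tab, "chest", "age_group")$value, 1.0)
  expect_error(relative_coefficient(tab, "head", "age_group"),
               class = "peddose_error_insufficient_strata")
})

test_that("empty input and unreachable min_n are signalled", {
  expect_error(derive_coefficients(make_scans(0), axes = "age_group"),
               class = "peddose_error_empty_input")
  scans <- make_scans(4, e_reference = 5)
  expect_warning(tab <- derive_coefficients(scans, min_n = 10),
                 class = "peddose_warning_empty_table")
  expect_equal(nrow(tab), 0)
})

test_that("derived medians recover the generating coefficients", {
  cfg <- synthetic_config(seed = 31)
  reg <- generate_registry(cfg, per_stratum_n = 2000)
  tab <- derive_coefficients(reg, axes = "age_group")
  kt <- cfg$k_true
  m <- match(paste(tab$body_region, tab$age_group),
             paste(kt$body_region, kt$age_group))
  expect_false(any(is.na(m)))
  rel_err <- abs(tab$median_k - kt$median_k[m]) / kt$median_k[m]
  expect_lt(max(rel_err), 0.05)
})
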