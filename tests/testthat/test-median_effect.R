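test_that("fa_from_dose matches the closed form on frozen cases", {
  expect_equal(fa_from_dose(median_effect_params(6.54, 2), 6.54), 0.5)
  expect_equal(fa_from_dose(median_effect_params(6.54, 1), 13.08), 2 / 3,
               tolerance = 1e-12)
  # deep tail: (D/Dm)^m = 1e-9 dominates, fa ~ 1e-9
  expect_equal(fa_from_dose(median_effect_params(5.6, 3), 0.0056),
               1e-9 / (1 + 1e-9), tolerance = 1e-12)
})

test_that("fa_from_dose is strictly monotone with correct limits", {
  set.seed(11)
  for (i in 1:20) {
    p <- median_effect_params(stats::runif(1, 0.1, 200),
                              stats::runif(1, 0.5, 4))
    doses <- sort(10^stats::runif(25, -4, 4))
    fa <- fa_from_dose(p, doses)
    expect_true(all(diff(fa) > 0))
    expect_true(all(fa > 0 & fa < 1))
  }
  p <- median_effect_params(5, 2)
  expect_lt(fa_from_dose(p, 1e-12), 1e-20)
  expect_gt(fa_from_dose(p, 1e6), 1 - 1e-10)
  expect_lt(fa_from_dose(p, 1e6), 1)
})

test_that("dose_for_fa inverts fa_from_dose and honours Dm at fa = 0.5", {
  for (m in c(0.7, 1, 2.6)) {
    expect_equal(dose_for_fa(median_effect_params(5.53, m), 0.5), 5.53)
  }
  expect_equal(dose_for_fa(median_effect_params(7.88, 1), 0.75), 23.64,
               tolerance = 1e-12)
  set.seed(22)
  for (i in 1:25) {
    p <- median_effect_params(stats::runif(1, 0.1, 200),
                              stats::runif(1, 0.5, 4))
    D <- 10^stats::runif(1, -3, 3)
    expect_lt(abs(dose_for_fa(p, fa_from_dose(p, D)) - D) / D, 1e-9)
  }
})

test_that("domain violations raise classed errors", {
  p <- median_effect_params(5, 2)
  expect_error(fa_from_dose(p, 0), class = "synergyci_invalid_argument")
  expect_error(fa_from_dose(p, -1), class = "synergyci_invalid_argument")
  expect_error(dose_for_fa(p, 0), class = "synergyci_out_of_domain")
  expect_error(dose_for_fa(p, 1), class = "synergyci_out_of_domain")
  expect_error(median_effect_params(-1, 2),
               class = "synergyci_invalid_argument")
  expect_error(median_effect_params(5, 0),
               class = "synergyci_invalid_argument")
})

test_that("fit recovers noiseless curves exactly", {
  pts <- noiseless_points(5.6, 2.0, c(1, 2, 4, 8, 16, 32))
  fit <- fit_median_effect(pts)
  expect_equal(fit$dm, 5.6, tolerance = 1e-9)
  expect_equal(fit$m, 2.0, tolerance = 1e-9)
  expect_equal(fit$r, 1.0, tolerance = 1e-9)
  expect_identical(fit$n_used, 6L)

  set.seed(33)
  for (i in 1:15) {
    dm <- stats::runif(1, 0.1, 200)
    m <- stats::runif(1, 0.5, 4)
    doses <- dm * 2^seq(-3, 3)
    fit <- fit_median_effect(noiseless_points(dm, m, doses))
    expect_lt(abs(fit$dm - dm) / dm, 1e-6)
    expect_lt(abs(fit$m - m) / m, 1e-6)
    expect_equal(fit$r, 1, tolerance = 1e-9)
  }
})

test_that("fit equals the normal-equation oracle on small instances", {
  set.seed(44)
  for (i in 1:12) {
    n <- sample(3:10, 1)
    doses <- sort(10^stats::runif(n, -1, 2))
    fa <- pmin(pmax(fa_from_dose(median_effect_params(8, 1.5), doses) +
                      stats::rnorm(n, 0, 0.05), 0.01), 0.99)
    fit <- suppressWarnings(
      fit_median_effect(data.frame(dose = doses, fa = fa)))
    o <- ols_oracle(log10(doses), log10(fa / (1 - fa)))
    expect_equal(fit$m, o$slope, tolerance = 1e-8)
    expect_equal(-fit$m * log10(fit$dm), o$intercept, tolerance = 1e-8)
    expect_equal(fit$r, o$r, tolerance = 1e-8)
  }
})

test_that("two valid points give the exact interpolating line", {
  pts <- data.frame(dose = c(2, 8), fa = c(0.2, 0.7))
  fit <- fit_median_effect(pts)
  expect_equal(fa_from_dose(fit, c(2, 8)), c(0.2, 0.7), tolerance = 1e-10)
  expect_equal(abs(fit$r), 1, tolerance = 1e-12)
  expect_identical(fit$n_used, 2L)
})

test_that("boundary fa values are excluded, not clamped", {
  pts <- rbind(noiseless_points(5.6, 2, c(1, 2, 4, 8)),
               data.frame(drug = "d", dose = c(0.001, 1000), unit = "uM",
                          fa = c(0, 1)))
  fit <- fit_median_effect(pts)
  expect_identical(fit$n_used, 4L)
  expect_equal(fit$dm, 5.6, tolerance = 1e-9)
})

test_that("fit failure modes are classed", {
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2), fa = c(0, 1))),
    class = "synergyci_insufficient_data")
  expect_error(
    fit_median_effect(data.frame(dose = c(3, 3, 3), fa = c(0.2, 0.4, 0.6))),
    class = "synergyci_degenerate_design")
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2, 4), fa = c(0.8, 0.5, 0.2))),
    class = "synergyci_non_monotone")
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2), fa = c(0.2, 1.3))),
    class = "synergyci_invalid_argument")
  expect_error(
    fit_median_effect(data.frame(dose = 1:3,
                                 fa = c(0.1, 0.5, 0.9),
                                 unit = c("uM", "uM", "ug/mL"))),
    class = "synergyci_unit_mismatch")
  expect_warning(
    fit_median_effect(data.frame(dose = c(1, 2, 4, 8, 16),
                                 fa = c(0.4, 0.2, 0.5, 0.3, 0.6))),
    class = "synergyci_low_r")
})

test_that("dose-response CSV round-trips through the reader", {
  pts <- noiseless_points(5.6, 2, c(1, 4, 16), drug = "PSD")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(pts, path, row.names = FALSE)
  back <- read_dose_response(path)
  expect_equal(back$dose, pts$dose)
  expect_equal(back$fa, pts$fa)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(pts[, c("drug", "dose")], bad, row.names = FALSE)
  expect_error(read_dose_response(bad), class = "synergyci_schema_error")
})
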