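three_params <- function(m = c(2.0, 1.8, 2.4), unit = "ug/mL") {
  make_params(unname(fixture_dm), m, unit = unit, drugs = names(fixture_dm))
}

test_that("design_fixed_ratio derives Dm-proportional weights and the ladder", {
  d <- design_fixed_ratio(three_params(), dilution_factor = 1.5, n_levels = 6)
  expect_equal(d$weights, unname(fixture_dm) / sum(fixture_dm),
               tolerance = 1e-12)
  expect_equal(round(d$weights, 4), c(0.3278, 0.2772, 0.3950))
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_true(all(diff(d$total_doses) < 0))
  expect_equal(d$total_doses[-1] * 1.5, d$total_doses[-d$n_levels],
               tolerance = 1e-12)
  # sum(Dm) sits at an interior ladder level
  idx <- which(abs(d$total_doses - sum(fixture_dm)) < 1e-9)
  expect_length(idx, 1)
  expect_true(idx > 1 && idx < d$n_levels)

  eq <- design_fixed_ratio(make_params(c(4, 4, 4), c(1, 2, 3)))
  expect_equal(eq$weights, rep(1 / 3, 3))

  top <- design_fixed_ratio(three_params(), dilution_factor = 1.5,
                            n_levels = 4, top_total_dose = 36)
  expect_equal(top$total_doses, c(36, 24, 16, 32 / 3), tolerance = 1e-12)

  mixed <- make_params(c(5, 6), c(1, 1))
  mixed[[2]]$unit <- "uM"
  mixed[[1]]$unit <- "ug/mL"
  expect_error(design_fixed_ratio(mixed), class = "synergyci_unit_mismatch")
  expect_error(design_fixed_ratio(three_params(), dilution_factor = 1),
               class = "synergyci_invalid_argument")
})

test_that("combination_index at fa = 0.5 reduces to sum(d_j / Dm_j)", {
  total <- fixture_combo_dm
  doses <- total * unname(fixture_dm) / sum(fixture_dm)
  for (m in list(c(1, 1, 1), c(2, 1.8, 2.4), c(0.6, 3.5, 1.1))) {
    ci <- combination_index(three_params(m), doses, 0.5)
    expect_equal(ci, 3 * total / sum(fixture_dm), tolerance = 1e-12)
  }
  expect_equal(3 * total / sum(fixture_dm), 0.5594, tolerance = 1e-4)
})

test_that("CI is linear in doses and unit-invariant", {
  ps <- three_params()
  d <- c(2, 1.5, 3)
  ci1 <- combination_index(ps, d, 0.4)
  expect_equal(combination_index(ps, 2 * d, 0.4), 2 * ci1, tolerance = 1e-12)
  # common rescaling of all doses and Dm values cancels
  ps_scaled <- make_params(unname(fixture_dm) * 1000, c(2.0, 1.8, 2.4),
                           unit = "ng/mL", drugs = names(fixture_dm))
  expect_equal(combination_index(ps_scaled, d * 1000, 0.4), ci1,
               tolerance = 1e-12)
})

test_that("a sham self-combination is exactly additive at every fa", {
  p <- median_effect_params(5.6, 2.2, drug = "solo")
  two <- list(p, median_effect_params(5.6, 2.2, drug = "solo"))
  for (w in list(c(0.5, 0.5), c(0.2, 0.8))) {
    for (D in c(1, 5.6, 20)) {
      fa <- fa_from_dose(p, D)
      expect_equal(combination_index(two, w * D, fa), 1, tolerance = 1e-9)
    }
  }
})

test_that("combination_index rejects malformed input", {
  ps <- three_params()
  expect_error(combination_index(ps, c(1, 2), 0.5),
               class = "synergyci_invalid_argument")
  expect_error(combination_index(ps, c(1, 2, -3), 0.5),
               class = "synergyci_invalid_argument")
  expect_error(combination_index(ps, c(1, 2, 3), 1),
               class = "synergyci_out_of_domain")
})

test_that("fit_combination_as_single recovers mixture parameters", {
  p <- median_effect_params(fixture_combo_dm, 1.8, unit = "ug/mL")
  total <- fixture_combo_dm * 1.5^seq(-3, 3)
  obs <- data.frame(total_dose = total, fa = fa_from_dose(p, total))
  fit <- fit_combination_as_single(obs, unit = "ug/mL")
  expect_equal(fit$dm, fixture_combo_dm, tolerance = 1e-9)
  expect_equal(fit$m, 1.8, tolerance = 1e-9)
  expect_identical(fit$drug, "combination")
  # boundary rows are dropped
  obs2 <- rbind(obs, data.frame(total_dose = c(1e-9, 1e9), fa = c(0, 1)))
  expect_identical(fit_combination_as_single(obs2)$n_used, 7L)
  expect_error(fit_combination_as_single(data.frame(fa = 0.5)),
               class = "synergyci_schema_error")
})

test_that("fa_ci_curve reports CI = 1 for a sham design and the closed form at fa = 0.5", {
  p <- median_effect_params(5.6, 2.2, drug = "solo")
  sham <- list(p, median_effect_params(5.6, 2.2, drug = "solo"))
  des <- design_fixed_ratio(sham, n_levels = 4)
  curve <- fa_ci_curve(sham, p, des)
  expect_equal(curve$ci, rep(1, nrow(curve)), tolerance = 1e-9)

  ps <- three_params()
  combo <- median_effect_params(fixture_combo_dm, 1.8, unit = "ug/mL")
  des3 <- design_fixed_ratio(ps)
  one <- fa_ci_curve(ps, combo, des3, fa_grid = 0.5)
  expect_equal(one$ci, 3 * fixture_combo_dm / sum(fixture_dm),
               tolerance = 1e-12)
  expect_equal(one$total_dose, fixture_combo_dm, tolerance = 1e-12)
  expect_error(fa_ci_curve(ps, combo, des3, fa_grid = c(0.5, 1)),
               class = "synergyci_out_of_domain")
})

test_that("ci_table scores observed levels and classifies them", {
  ps <- three_params()
  obs <- data.frame(PSD = c(1.22, 2.44), R13 = c(1.03, 2.06),
                    PSA = c(1.47, 2.94), fa = c(0.5, 0.8))
  tab <- ci_table(ps, obs)
  expect_s3_class(tab, "ci_table")
  expect_equal(tab$ci[1],
               combination_index(ps, c(1.22, 1.03, 1.47), 0.5),
               tolerance = 1e-12)
  expect_identical(tab$verdict, classify_ci(tab$ci))
  expect_error(ci_table(ps, obs[, -4]), class = "synergyci_schema_error")
})

test_that("classify_ci reproduces the published bands", {
  expect_identical(classify_ci(0.27), "strong synergism")
  expect_identical(classify_ci(0.52), "synergism")
  expect_identical(classify_ci(1.0), "nearly additive")
  expect_identical(classify_ci(0.02), "very strong synergism")
  expect_identical(classify_ci(0.75), "moderate synergism")
  expect_identical(classify_ci(0.87), "slight synergism")
  expect_identical(classify_ci(1.15), "slight antagonism")
  expect_identical(classify_ci(2.0), "antagonism")
  expect_identical(classify_ci(10), "strong antagonism")
})

test_that("classification bands tile (0, Inf): half-open, lower-inclusive", {
  eps <- 1e-12
  bounds <- c(0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 3.3)
  below <- classify_ci(bounds - eps)
  at <- classify_ci(bounds)
  expect_true(all(below != at))       # every boundary switches bands
  grid <- exp(seq(log(1e-6), log(1e6), length.out = 4001))
  lab <- classify_ci(grid)
  expect_false(anyNA(lab))            # no gaps anywhere on (0, Inf)
  expect_identical(rle(lab)$values, c("very strong synergism",
                                      "strong synergism", "synergism",
                                      "moderate synergism",
                                      "slight synergism", "nearly additive",
                                      "slight antagonism", "antagonism",
                                      "strong antagonism"))
  expect_error(classify_ci(0), class = "synergyci_invalid_argument")
  expect_error(classify_ci(-1), class = "synergyci_invalid_argument")
})
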