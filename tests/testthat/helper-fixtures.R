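# Shared fixtures and independent oracles.

# Potencies reported for the three-saponin worked example (ug/mL):
# singles 6.54, 5.53, 7.88; mixture 3.72 on total dose.
fixture_dm <- c(PSD = 6.54, R13 = 5.53, PSA = 7.88)
fixture_combo_dm <- 3.72

make_params <- function(dm, m, unit = "uM", drugs = NULL) {
  if (is.null(drugs)) drugs <- paste0("drug", seq_along(dm))
  Map(function(a, b, d) median_effect_params(a, b, unit = unit, drug = d),
      dm, m, drugs)
}

# Independent least-squares oracle: explicit normal equations from raw sums,
# no lm machinery shared with the implementation.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# Exhaustive hypergeometric enumeration: probability of k or more hits when
# drawing n from a universe of N with K marked, by direct combinatorial count.
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

noiseless_points <- function(dm, m, doses, unit = "uM", drug = "d") {
  p <- median_effect_params(dm, m, unit = unit)
  data.frame(drug = drug, dose = doses, unit = unit,
             fa = fa_from_dose(p, doses), stringsAsFactors = FALSE)
}
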