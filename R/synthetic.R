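# Synthetic data with known ground truth: single-drug median-effect curves,
# fixed-ratio mixtures with a prescribed true CI profile kappa(fa), and
# planted differential-protein tables.  Everything is seeded and
# deterministic, so fitting, CI recovery and the screen are testable end to
# end without any external data.

#' Simulate single-drug dose-response points
#'
#' Noiseless mode returns points lying exactly on the median-effect curve
#' `fa = 1/(1 + (Dm/D)^m)`. Noisy mode adds independent additive Gaussian
#' noise (SD `sigma`) to `fa` per replicate and truncates to `[0, 1]` —
#' noise lives in the model's natural effect space, mimicking well-to-well
#' MTT variability after normalization.
#'
#' @param dm,m True median-effect dose and slope.
#' @param doses Vector of positive doses.
#' @param unit Concentration-unit tag.
#' @param sigma Additive noise SD on `fa` (0 = noiseless).
#' @param replicates Replicate wells per dose (default 1).
#' @param seed Integer seed; required when `sigma > 0` for reproducibility.
#' @param drug Drug label for the output table.
#' @param as_plate If `TRUE`, return raw OD490 plate rows (roles `sample`,
#'   `control`, `blank`) instead of `(dose, fa)` points, so the viability
#'   module can be exercised from absorbances.
#' @param control_od,blank_od Plate constants used when `as_plate = TRUE`;
#'   sample OD is `blank + (control - blank) * (1 - fa)`.
#' @return Data frame of dose-response points (`drug, dose, unit, replicate,
#'   fa`) or of plate rows when `as_plate = TRUE`.
#' @examples
#' simulate_single_drug(5.6, 2, doses = 2^(0:5))
#' @export
simulate_single_drug <- function(dm, m, doses, unit = "uM", sigma = 0,
                                 replicates = 1L, seed = NULL, drug = "drug",
                                 as_plate = FALSE, control_od = 1.8,
                                 blank_od = 0.1) {
  stopifnot_scalar_number(dm, "dm", positive = TRUE)
  stopifnot_scalar_number(m, "m", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma")
  if (sigma < 0) synergyci_stop("`sigma` must be >= 0", "invalid_argument")
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    synergyci_stop("`doses` must be positive", "invalid_argument")
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    synergyci_stop("`replicates` must be >= 1", "invalid_argument")
  }
  if (sigma > 0) {
    if (is.null(seed)) {
      synergyci_stop("a `seed` is required when `sigma > 0`",
                     "invalid_argument")
    }
    set.seed(as.integer(seed))
  }
  p <- median_effect_params(dm, m, unit = unit, drug = drug)
  grid <- expand.grid(replicate = seq_len(replicates), dose = doses,
                      KEEP.OUT.ATTRS = FALSE)
  fa <- fa_from_dose(p, grid$dose)
  if (sigma > 0) fa <- pmin(pmax(fa + stats::rnorm(length(fa), 0, sigma), 0), 1)
  pts <- data.frame(drug = drug, dose = grid$dose, unit = unit,
                    replicate = grid$replicate, fa = fa,
                    stringsAsFactors = FALSE)
  if (!as_plate) return(pts)
  if (control_od <= blank_od) {
    synergyci_stop("`control_od` must exceed `blank_od`", "invalid_plate")
  }
  sample_rows <- data.frame(
    drug = drug, dose = pts$dose, unit = unit, replicate = pts$replicate,
    role = "sample",
    od490 = blank_od + (control_od - blank_od) * (1 - pts$fa),
    stringsAsFactors = FALSE)
  ctrl_rows <- data.frame(
    drug = drug, dose = NA_real_, unit = unit,
    replicate = seq_len(replicates),
    role = rep(c("control", "blank"), each = replicates),
    od490 = rep(c(control_od, blank_od), each = replicates),
    stringsAsFactors = FALSE)
  rbind(sample_rows, ctrl_rows)
}

# Loewe-additive total dose at effect level fa for weights w and single-drug
# params: D_add(fa) = 1 / sum_j w_j / Dx_j(fa).  A mixture whose true CI is
# kappa reaches fa at total dose kappa * D_add(fa).
loewe_additive_dose <- function(single_params, weights, fa) {
  dx <- vapply(single_params, dose_for_fa, numeric(length(fa)), fa = fa)
  if (is.null(dim(dx))) dx <- matrix(dx, nrow = 1L)
  1 / as.numeric(dx^(-1) %*% weights)
}

# Invert D = kappa(fa) * D_add(fa) for fa by bisection on [1e-6, 1 - 1e-6].
# The right-hand side is strictly increasing in fa (each Dx_j is), so the
# root is unique when it is bracketed.
solve_fa_for_total_dose <- function(single_params, weights, kappa_fun,
                                    total_dose, tol = 1e-10) {
  g <- function(fa) {
    kappa_fun(fa) * loewe_additive_dose(single_params, weights, fa) -
      total_dose
  }
  lo <- 1e-6
  hi <- 1 - 1e-6
  glo <- g(lo)
  ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo > 0 || ghi < 0) {
    synergyci_stop(sprintf(
      "cannot bracket fa for total dose %g: g(%g) = %g, g(%g) = %g (is kappa(fa) monotone-compatible?)",
      total_dose, lo, glo, hi, ghi), "numerical")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Simulate fixed-ratio combination observations with a known CI profile
#'
#' Constructs mixture data whose ground-truth combination index is the
#' prescribed `kappa`: at effect level `fa` the Loewe-additive mixture needs
#' total dose `D_add(fa) = (sum_j w_j / Dx_j(fa))^-1`, and the simulated
#' mixture reaches `fa` at `kappa * D_add(fa)`. For each requested total
#' dose the achieved `fa` is found by monotone bisection on this relation
#' (bracket `[1e-6, 1 - 1e-6]`, tolerance 1e-10). Running the full CI
#' pipeline on the output therefore recovers `CI ~ kappa` — with `kappa = 1`
#' the mixture is exactly Loewe-additive.
#'
#' @param single_params List of single-drug [median_effect_params()]
#'   (ground truth).
#' @param weights Positive component weights summing to 1; default
#'   Dm-proportional as in [design_fixed_ratio()].
#' @param kappa True CI: a positive constant or a function of `fa`.
#' @param total_doses Total mixture doses to observe; default an 8-level
#'   1:1.5 serial-dilution ladder centred on the simulated mixture's own
#'   median-effect total dose `kappa * D_add(0.5)`, so the observed `fa`
#'   span the informative part of the curve whatever `kappa` is.
#' @param sigma,replicates,seed Noise model as in [simulate_single_drug()].
#' @return Data frame with one dose column per component plus `total_dose`,
#'   `replicate`, `fa` (and `fa_true`, the noiseless effect).
#' @examples
#' ps <- list(median_effect_params(6.54, 2), median_effect_params(5.53, 1.8),
#'            median_effect_params(7.88, 2.4))
#' sim <- simulate_combination(ps, kappa = 0.5)
#' @export
simulate_combination <- function(single_params, weights = NULL, kappa = 1,
                                 total_doses = NULL, sigma = 0,
                                 replicates = 1L, seed = NULL) {
  check_params_list(single_params)
  dm <- vapply(single_params, `[[`, numeric(1), "dm")
  if (is.null(weights)) weights <- dm / sum(dm)
  if (length(weights) != length(single_params) || any(weights <= 0)) {
    synergyci_stop("`weights` must be positive, one per drug",
                   "invalid_argument")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    synergyci_stop("`weights` must sum to 1", "invalid_argument")
  }
  kappa_fun <- if (is.function(kappa)) {
    kappa
  } else {
    stopifnot_scalar_number(kappa, "kappa", positive = TRUE)
    function(fa) kappa
  }
  if (is.null(total_doses)) {
    # centre the ladder on the mixture's median-effect total dose so the
    # response range is sampled informatively for any kappa
    n_levels <- 8L
    d_mid <- kappa_fun(0.5) *
      loewe_additive_dose(single_params, weights, 0.5)
    top <- d_mid * 1.5^((n_levels - 1L) %/% 2L)
    total_doses <- top / 1.5^(seq_len(n_levels) - 1L)
  }
  if (any(!is.finite(total_doses)) || any(total_doses <= 0)) {
    synergyci_stop("`total_doses` must be positive", "invalid_argument")
  }
  replicates <- as.integer(replicates)
  if (sigma > 0) {
    if (is.null(seed)) {
      synergyci_stop("a `seed` is required when `sigma > 0`",
                     "invalid_argument")
    }
    set.seed(as.integer(seed))
  }
  fa_true <- vapply(total_doses, function(D) {
    solve_fa_for_total_dose(single_params, weights, kappa_fun, D)
  }, numeric(1))

  grid <- expand.grid(replicate = seq_len(replicates),
                      level = seq_along(total_doses),
                      KEEP.OUT.ATTRS = FALSE)
  fa <- fa_true[grid$level]
  if (sigma > 0) fa <- pmin(pmax(fa + stats::rnorm(length(fa), 0, sigma), 0), 1)

  components <- vapply(seq_along(single_params), function(j) {
    d <- single_params[[j]]$drug
    if (is.na(d)) paste0("drug", j) else d
  }, character(1))
  comp <- outer(total_doses[grid$level], weights)
  colnames(comp) <- components
  out <- data.frame(total_dose = total_doses[grid$level],
                    replicate = grid$replicate,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(comp, check.names = FALSE))
  out$fa_true <- fa_true[grid$level]
  out$fa <- fa
  out[order(out$total_dose, out$replicate), , drop = FALSE]
}

#' Simulate a protein fold-change table with planted regulation
#'
#' Plants `round(n * frac_up)` up-regulated proteins (fold change strictly
#' above 1.5), `round(n * frac_down)` down-regulated ones (strictly below
#' 0.67), and fills the rest with nulls whose log2 fold change is truncated
#' Gaussian noise small enough never to cross either threshold — so the
#' differential screen recovers the planted sets exactly.
#'
#' @param n Number of proteins.
#' @param frac_up,frac_down Planted fractions; `frac_up + frac_down <= 1`.
#' @param effect_size Upper bound of the planted extra log2-fold-change
#'   spread beyond the threshold (default 1.5).
#' @param seed Integer seed.
#' @return Data frame `id, fold_change, status` where `status` is the
#'   ground-truth label (`up`, `down`, `null`).
#' @export
simulate_protein_table <- function(n, frac_up = 0.1, frac_down = 0.06,
                                   effect_size = 1.5, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    synergyci_stop("`n` must be a positive integer", "invalid_argument")
  }
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    synergyci_stop("need frac_up, frac_down >= 0 and frac_up + frac_down <= 1",
                   "invalid_argument")
  }
  stopifnot_scalar_number(effect_size, "effect_size", positive = TRUE)
  set.seed(as.integer(seed))
  n_up <- round(n * frac_up)
  n_down <- round(n * frac_down)
  n_null <- n - n_up - n_down

  # planted: margin of at least 0.1 log2 units beyond the threshold;
  # nulls: truncated at +/-0.5 log2, safely inside (0.67, 1.5)
  l2_up <- log2(1.5) + 0.1 + stats::runif(n_up, 0, effect_size)
  l2_down <- log2(0.67) - 0.1 - stats::runif(n_down, 0, effect_size)
  l2_null <- pmin(pmax(stats::rnorm(n_null, 0, 0.15), -0.5), 0.5)

  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    fold_change = 2^c(l2_up, l2_down, l2_null),
    status = rep(c("up", "down", "null"), c(n_up, n_down, n_null)),
    stringsAsFactors = FALSE
  )
}
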