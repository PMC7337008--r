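# Fixed-ratio combination design, combination-index (CI) computation against
# the Loewe-additivity null, Fa-CI curves, and synergy classification.
#
# CI at effect level fa for component doses d_j:
#   CI = sum_j d_j / Dx_j(fa),   Dx_j(fa) = dose of drug j alone giving fa.
# CI < 1 synergism, CI = 1 additivity, CI > 1 antagonism.

#' Design a fixed-ratio combination
#'
#' The Chou-Talalay CI framework requires all combination dose levels to
#' share one component ratio. Components are mixed in proportion to their
#' single-drug potency: weight `w_j = Dm_j / sum(Dm)`, so the mixture at
#' total dose `sum(Dm)` delivers each drug exactly at its own median-effect
#' dose. Dose levels form a serial-dilution ladder
#' `top, top/f, top/f^2, ...`; when `top_total_dose` is not given the ladder
#' is centred so that `sum(Dm)` sits at an interior level.
#'
#' @param single_params List of [median_effect_params()], one per drug; all
#'   must share one unit.
#' @param dilution_factor Serial dilution factor `f > 1` (default 1.5).
#' @param n_levels Number of dose levels (`>= 2`).
#' @param top_total_dose Optional highest total mixture dose; defaults to
#'   centring `sum(Dm)` in the ladder.
#' @return A `fixed_ratio_design` object: component labels, weights, unit,
#'   total-dose ladder and per-component dose matrix.
#' @examples
#' ps <- list(median_effect_params(6.54, 2, unit = "ug/mL", drug = "PSD"),
#'            median_effect_params(5.53, 2, unit = "ug/mL", drug = "R13"),
#'            median_effect_params(7.88, 2, unit = "ug/mL", drug = "PSA"))
#' design_fixed_ratio(ps, dilution_factor = 1.5, n_levels = 6)
#' @export
design_fixed_ratio <- function(single_params, dilution_factor = 1.5,
                               n_levels = 6L, top_total_dose = NULL) {
  check_params_list(single_params)
  stopifnot_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) {
    synergyci_stop("`dilution_factor` must be > 1", "invalid_argument")
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) {
    synergyci_stop("`n_levels` must be an integer >= 2", "invalid_argument")
  }
  dm <- vapply(single_params, `[[`, numeric(1), "dm")
  weights <- dm / sum(dm)
  unit <- single_params[[1]]$unit
  components <- vapply(seq_along(single_params), function(j) {
    d <- single_params[[j]]$drug
    if (is.na(d)) paste0("drug", j) else d
  }, character(1))

  if (is.null(top_total_dose)) {
    # place sum(Dm) at an interior ladder level (never first or last)
    centre <- max(1L, min(n_levels - 2L, (n_levels - 1L) %/% 2L))
    top_total_dose <- sum(dm) * dilution_factor^centre
  }
  stopifnot_scalar_number(top_total_dose, "top_total_dose", positive = TRUE)

  totals <- top_total_dose / dilution_factor^(seq_len(n_levels) - 1L)
  doses <- outer(totals, weights)
  colnames(doses) <- components
  structure(
    list(components = components, weights = weights, unit = unit,
         dilution_factor = dilution_factor, n_levels = n_levels,
         top_total_dose = top_total_dose, total_doses = totals,
         component_doses = doses),
    class = "fixed_ratio_design"
  )
}

#' @export
print.fixed_ratio_design <- function(x, ...) {
  cat(sprintf("Fixed-ratio design: %s (weights %s), %d levels, 1:%g dilution, top total %.4g %s\n",
              paste(x$components, collapse = " + "),
              paste(sprintf("%.4f", x$weights), collapse = ":"),
              x$n_levels, x$dilution_factor, x$top_total_dose, x$unit))
  invisible(x)
}

check_params_list <- function(single_params) {
  if (!is.list(single_params) || length(single_params) < 1L ||
      !all(vapply(single_params, is_median_effect_params, logical(1)))) {
    synergyci_stop("`single_params` must be a list of `median_effect_params`",
                   "invalid_argument")
  }
  units <- vapply(single_params, `[[`, character(1), "unit")
  if (length(unique(units)) > 1L) {
    synergyci_stop(paste0("mixed concentration units across drugs: ",
                          paste(unique(units), collapse = ", ")),
                   "unit_mismatch")
  }
  invisible(single_params)
}

#' Combination index at an observed effect level
#'
#' `CI = sum_j d_j / Dx_j(fa)` where `d_j` is the dose of drug `j` actually
#' given in the mixture and `Dx_j(fa)` the dose of drug `j` alone that would
#' produce the same fraction affected (via [dose_for_fa()]).
#'
#' @param single_params List of [median_effect_params()], one per drug.
#' @param component_doses Positive doses given in combination, one per drug,
#'   in the parameters' shared unit.
#' @param fa_observed Fraction affected achieved by the mixture, strictly in
#'   `(0, 1)`.
#' @return The combination index, a positive scalar.
#' @examples
#' ps <- list(median_effect_params(6.54, 2), median_effect_params(5.53, 1.5),
#'            median_effect_params(7.88, 3))
#' # at fa = 0.5 every Dx equals Dm, whatever the slopes
#' combination_index(ps, c(1.22, 1.03, 1.47), 0.5)
#' @export
combination_index <- function(single_params, component_doses, fa_observed) {
  check_params_list(single_params)
  if (length(component_doses) != length(single_params)) {
    synergyci_stop(sprintf(
      "got %d component doses for %d drugs", length(component_doses),
      length(single_params)), "invalid_argument")
  }
  if (any(!is.finite(component_doses)) || any(component_doses <= 0)) {
    synergyci_stop("component doses must be positive", "invalid_argument")
  }
  stopifnot_scalar_number(fa_observed, "fa_observed")
  dx <- vapply(single_params, dose_for_fa, numeric(1), fa = fa_observed)
  sum(component_doses / dx)
}

#' Fit the mixture as a single agent
#'
#' Under a fixed-ratio design the mixture is treated as one drug dosed by
#' its TOTAL concentration; its own `(Dm, m)` come from the same
#' median-effect fit as any single agent.
#'
#' @param observations Data frame with columns `total_dose` (or `dose`) and
#'   `fa`; optional `unit`.
#' @param unit Concentration-unit tag (default from the data or `"uM"`).
#' @return A [median_effect_params()] object for the mixture.
#' @export
fit_combination_as_single <- function(observations, unit = NULL) {
  if (!is.data.frame(observations)) {
    synergyci_stop("`observations` must be a data frame", "schema_error")
  }
  if (!"dose" %in% names(observations)) {
    if (!"total_dose" %in% names(observations)) {
      synergyci_stop("`observations` needs a `total_dose` (or `dose`) column",
                     "schema_error")
    }
    observations$dose <- observations$total_dose
  }
  fit_median_effect(observations, unit = unit, drug = "combination")
}

#' Fa-CI curve over an effect-level grid
#'
#' For each `fa` on the grid, the total mixture dose producing that effect
#' is read off the fitted combination curve, split into component doses by
#' the design weights, and scored with [combination_index()]. This is the
#' standard synergy summary: CI as a function of the fraction affected.
#'
#' @param single_params List of single-drug [median_effect_params()].
#' @param combo_params [median_effect_params()] of the mixture fitted on
#'   total dose ([fit_combination_as_single()]).
#' @param design A `fixed_ratio_design` (only its weights are used).
#' @param fa_grid Effect levels strictly inside `(0, 1)`;
#'   default `seq(0.05, 0.95, by = 0.05)`.
#' @return Data frame with columns `fa`, `total_dose`, one dose column per
#'   component, and `ci`.
#' @export
fa_ci_curve <- function(single_params, combo_params, design,
                        fa_grid = seq(0.05, 0.95, by = 0.05)) {
  check_params_list(single_params)
  assert_params(combo_params)
  if (!inherits(design, "fixed_ratio_design")) {
    synergyci_stop("`design` must be a `fixed_ratio_design`",
                   "invalid_argument")
  }
  if (length(fa_grid) < 1L || any(fa_grid <= 0) || any(fa_grid >= 1)) {
    synergyci_stop("`fa_grid` must lie strictly inside (0, 1)",
                   "out_of_domain")
  }
  total <- dose_for_fa(combo_params, fa_grid)
  comp <- outer(total, design$weights)
  colnames(comp) <- design$components
  ci <- vapply(seq_along(fa_grid), function(i) {
    combination_index(single_params, comp[i, ], fa_grid[i])
  }, numeric(1))
  out <- data.frame(fa = fa_grid, total_dose = total,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(comp, check.names = FALSE))
  out$ci <- ci
  out
}

#' Combination-index table at observed dose levels
#'
#' Scores each observed combination dose level with the CI computed at the
#' OBSERVED fraction affected of that level (as opposed to the fitted-curve
#' CI of [fa_ci_curve()]; both views are conventional and both are exposed).
#'
#' @param single_params List of single-drug [median_effect_params()].
#' @param observations Data frame: one dose column per component (named as
#'   the drugs) plus an `fa` column.
#' Rows whose observed `fa` sits on a boundary (0 or 1, e.g. after noisy
#' plates were truncated) have no defined CI and are excluded; the count of
#' exclusions is attached as attribute `n_excluded`.
#'
#' @param components Character vector naming the dose columns, in the order
#'   of `single_params`; defaults to the drug labels in `single_params`.
#' @return A `ci_table` data frame: component doses, `fa`, `ci`, `verdict`.
#' @export
ci_table <- function(single_params, observations, components = NULL) {
  check_params_list(single_params)
  if (is.null(components)) {
    components <- vapply(seq_along(single_params), function(j) {
      d <- single_params[[j]]$drug
      if (is.na(d)) paste0("drug", j) else d
    }, character(1))
  }
  miss <- setdiff(c(components, "fa"), names(observations))
  if (length(miss)) {
    synergyci_stop(paste0("observations are missing column(s): ",
                          paste(miss, collapse = ", ")), "schema_error")
  }
  keep <- observations$fa > 0 & observations$fa < 1
  n_excluded <- sum(!keep)
  observations <- observations[keep, , drop = FALSE]
  ci <- vapply(seq_len(nrow(observations)), function(i) {
    combination_index(single_params,
                      as.numeric(observations[i, components]),
                      observations$fa[i])
  }, numeric(1))
  out <- observations[, c(components, "fa"), drop = FALSE]
  out$ci <- ci
  out$verdict <- if (length(ci)) classify_ci(ci) else character(0)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("ci_table", class(out))
  out
}

# Synergy bands: half-open, lower-inclusive, tiling (0, Inf).
ci_band_breaks <- c(0, 0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 3.3, Inf)
ci_band_labels <- c("very strong synergism", "strong synergism", "synergism",
                    "moderate synergism", "slight synergism",
                    "nearly additive", "slight antagonism", "antagonism",
                    "strong antagonism")

#' Classify a combination index into a synergy verdict
#'
#' Deterministic band lookup on half-open, lower-inclusive intervals that
#' tile `(0, Inf)`:
#' `(0,0.1)` very strong synergism, `[0.1,0.3)` strong synergism,
#' `[0.3,0.7)` synergism, `[0.7,0.85)` moderate synergism,
#' `[0.85,0.90)` slight synergism, `[0.90,1.10)` nearly additive
#' (contains the additive point CI = 1), `[1.10,1.20)` slight antagonism,
#' `[1.20,3.3)` antagonism, `[3.3,Inf)` strong antagonism.
#'
#' @param ci Vector of positive combination indices.
#' @return Character vector of verdict labels.
#' @examples
#' classify_ci(c(0.27, 0.52, 1.0, 1.63))
#' @export
classify_ci <- function(ci) {
  if (!is.numeric(ci) || length(ci) < 1L || any(!is.finite(ci)) ||
      any(ci <= 0)) {
    synergyci_stop("`ci` must be positive and finite", "invalid_argument")
  }
  idx <- findInterval(ci, ci_band_breaks, left.open = FALSE,
                      rightmost.closed = FALSE)
  ci_band_labels[idx]
}

#' Read combination observations from CSV
#'
#' One dose column per component plus an `fa` column (header required).
#'
#' @param path Path to the CSV file.
#' @return Data frame of combination observations.
#' @export
read_combination <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"fa" %in% names(df)) {
    synergyci_stop("combination CSV is missing column: fa", "schema_error")
  }
  df
}
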