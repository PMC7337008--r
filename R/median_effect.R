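# Median-effect model: fa/fu = (D/Dm)^m, the mass-action dose-effect law
# underlying the Chou-Talalay synergy framework.  Dm is the median-effect
# dose (the dose giving fa = 0.5, the role IC50 plays elsewhere), m the
# sigmoidicity exponent, and fa/fu the affected/unaffected fractions
# (fu = 1 - fa).

#' Construct median-effect parameters
#'
#' Bundles the fitted (or assumed) parameters of a median-effect
#' dose-response curve: the median-effect dose `dm` (potency, in the declared
#' concentration unit), the slope exponent `m` (shape: `m = 1` hyperbolic,
#' `m > 1` sigmoidal), and the correlation coefficient `r` of the
#' log-linearized median-effect plot when the object comes from a fit.
#'
#' @param dm Median-effect dose, a single positive number.
#' @param m Slope exponent, a single positive number.
#' @param r Correlation coefficient of the median-effect plot, in
#'   `[-1, 1]`; `NA` when not derived from data.
#' @param unit Concentration-unit tag (e.g. `"uM"`, `"ug/mL"`). Purely a
#'   label: no conversion is ever performed, but mixed units are rejected
#'   when parameter sets are combined.
#' @param n_used Number of observations retained by the fit (`NA` when the
#'   parameters were not fitted).
#' @param drug Optional drug label carried through tables and reports.
#' @return An object of class `median_effect_params`.
#' @examples
#' p <- median_effect_params(dm = 5.6, m = 2, unit = "uM")
#' fa_from_dose(p, 5.6) # 0.5 by definition of Dm
#' @export
median_effect_params <- function(dm, m, r = NA_real_, unit = "uM",
                                 n_used = NA_integer_, drug = NA_character_) {
  stopifnot_scalar_number(dm, "dm", positive = TRUE)
  stopifnot_scalar_number(m, "m", positive = TRUE)
  if (!is.na(r)) {
    stopifnot_scalar_number(r, "r")
    if (abs(r) > 1 + 1e-12) {
      synergyci_stop("`r` must lie in [-1, 1]", "invalid_argument")
    }
  }
  if (!is.na(n_used) && n_used < 2) {
    synergyci_stop("`n_used` must be >= 2 for a fitted curve",
                   "invalid_argument")
  }
  structure(
    list(dm = as.numeric(dm), m = as.numeric(m), r = as.numeric(r),
         unit = as.character(unit), n_used = as.integer(n_used),
         drug = as.character(drug)),
    class = "median_effect_params"
  )
}

#' @export
print.median_effect_params <- function(x, ...) {
  lbl <- if (is.na(x$drug)) "" else paste0(" [", x$drug, "]")
  cat(sprintf("Median-effect parameters%s: Dm = %.4g %s, m = %.4g", lbl,
              x$dm, x$unit, x$m))
  if (!is.na(x$r)) cat(sprintf(", r = %.4f", x$r))
  if (!is.na(x$n_used)) cat(sprintf(" (n = %d)", x$n_used))
  cat("\n")
  invisible(x)
}

is_median_effect_params <- function(x) inherits(x, "median_effect_params")

assert_params <- function(params) {
  if (!is_median_effect_params(params)) {
    synergyci_stop("`params` must be a `median_effect_params` object",
                   "invalid_argument")
  }
  invisible(params)
}

#' Fraction affected at a dose
#'
#' Evaluates the median-effect curve in its closed form
#' `fa = 1 / (1 + (Dm/D)^m)`, the rearrangement of `fa/fu = (D/Dm)^m`.
#'
#' @param params A [median_effect_params()] object.
#' @param dose Vector of positive doses in the parameters' unit.
#' @return Fraction(s) affected, strictly inside `(0, 1)`.
#' @examples
#' p <- median_effect_params(6.54, 2)
#' fa_from_dose(p, c(3, 6.54, 13))
#' @export
fa_from_dose <- function(params, dose) {
  assert_params(params)
  if (!is.numeric(dose) || length(dose) < 1L || any(!is.finite(dose)) ||
      any(dose <= 0)) {
    synergyci_stop("`dose` must be positive and finite", "invalid_argument")
  }
  # computed on the log scale to stay stable at extreme dose/Dm ratios
  1 / (1 + exp(params$m * (log(params$dm) - log(dose))))
}

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect curve: `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#' This `Dx` is the per-drug denominator of the combination index.
#'
#' @inheritParams fa_from_dose
#' @param fa Vector of target fractions affected, strictly inside `(0, 1)`.
#' @return Positive dose(s) in the parameters' unit.
#' @examples
#' p <- median_effect_params(7.88, 1)
#' dose_for_fa(p, 0.75) # 3 * Dm when m = 1
#' @export
dose_for_fa <- function(params, fa) {
  assert_params(params)
  if (!is.numeric(fa) || length(fa) < 1L || any(!is.finite(fa)) ||
      any(fa <= 0) || any(fa >= 1)) {
    synergyci_stop(
      "`fa` must lie strictly inside (0, 1): the dose is undefined at 0 and infinite at 1",
      "out_of_domain")
  }
  params$dm * (fa / (1 - fa))^(1 / params$m)
}

#' Fit the median-effect model to dose-response points
#'
#' Performs the classical median-effect-plot fit: ordinary least squares of
#' `y = log10(fa/fu)` on `x = log10(D)`. The slope is `m`, the intercept is
#' `-m * log10(Dm)`, and `r` is the Pearson correlation of `(x, y)` — the
#' linear-correlation goodness-of-fit the method conventionally reports.
#'
#' Points with `fa <= 0` or `fa >= 1` are excluded (the log transform is
#' undefined there), not clamped; `n_used` in the result counts the points
#' actually retained. Points are equally weighted. A warning of class
#' `synergyci_low_r` is raised when `|r| < 0.9`, but the fit is returned —
#' no quality cutoff is enforced.
#'
#' @param points A data frame with numeric columns `dose` (positive) and
#'   `fa`, optionally `unit` and `drug` columns (must be uniform).
#' @param unit Concentration-unit tag; taken from a `unit` column when
#'   present.
#' @param drug Optional drug label; taken from a `drug` column when present.
#' @return A [median_effect_params()] object with `r` and `n_used` set.
#' @examples
#' p0 <- median_effect_params(5.6, 2)
#' d <- c(1, 2, 4, 8, 16, 32)
#' fit_median_effect(data.frame(dose = d, fa = fa_from_dose(p0, d)))
#' @export
fit_median_effect <- function(points, unit = NULL, drug = NULL) {
  if (!is.data.frame(points) || !all(c("dose", "fa") %in% names(points))) {
    synergyci_stop("`points` must be a data frame with `dose` and `fa` columns",
                   "schema_error")
  }
  if ("unit" %in% names(points)) {
    u <- unique(as.character(points$unit))
    if (length(u) > 1L) {
      synergyci_stop("mixed units within one curve", "unit_mismatch")
    }
    if (is.null(unit)) unit <- u
  }
  if (is.null(unit)) unit <- "uM"
  if (is.null(drug) && "drug" %in% names(points)) {
    d <- unique(as.character(points$drug))
    if (length(d) == 1L) drug <- d
  }
  if (is.null(drug)) drug <- NA_character_

  dose <- as.numeric(points$dose)
  fa <- as.numeric(points$fa)
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    synergyci_stop("all doses must be positive and finite", "invalid_argument")
  }
  if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1)) {
    synergyci_stop("all `fa` must lie in [0, 1]; truncate at the viability stage first",
                   "invalid_argument")
  }

  keep <- fa > 0 & fa < 1
  n_used <- sum(keep)
  if (n_used < 2L) {
    synergyci_stop(sprintf(
      "need >= 2 points with fa strictly in (0,1); got %d usable of %d",
      n_used, length(fa)), "insufficient_data")
  }
  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  if (length(unique(x)) < 2L) {
    synergyci_stop("all retained doses identical: slope is unidentifiable",
                   "degenerate_design")
  }

  fit <- stats::lm.fit(cbind(intercept = 1, logdose = x), y)
  b <- unname(fit$coefficients["intercept"])
  m <- unname(fit$coefficients["logdose"])
  if (!is.finite(m) || m <= 0) {
    synergyci_stop(sprintf(
      "fitted slope m = %.4g is not positive: data are not monotone increasing with dose",
      m), "non_monotone")
  }
  r <- if (stats::sd(y) == 0) {
    # horizontal points: correlation undefined; a fitted slope > 0 with
    # sd(y) = 0 cannot happen, so this branch only serves exact 2-point ties
    1
  } else {
    stats::cor(x, y)
  }
  dm <- 10^(-b / m)
  if (abs(r) < 0.9) {
    synergyci_warn(sprintf(
      "median-effect plot correlation |r| = %.3f < 0.9: fit quality is poor",
      abs(r)), "low_r")
  }
  median_effect_params(dm = dm, m = m, r = r, unit = unit,
                       n_used = n_used, drug = drug)
}

#' Pool replicate dose-response observations
#'
#' Averages `fa` across replicates of the same dose before fitting
#' (average-then-fit, the convention adopted throughout this package), and
#' truncates the pooled mean to `[0, 1]`. Grouping uses every column except
#' `fa`, `replicate` and other per-well noise columns, so it works for both
#' single-drug tables (grouped by `drug`/`dose`) and combination tables
#' (grouped by the component dose columns and `total_dose`).
#'
#' @param points Data frame with an `fa` column and dose/label columns.
#' @return One row per unique dose group with the pooled `fa` and a
#'   replicate count `n`.
#' @export
pool_replicates <- function(points) {
  if (!is.data.frame(points) || !"fa" %in% names(points)) {
    synergyci_stop("`points` must be a data frame with an `fa` column",
                   "schema_error")
  }
  keys <- setdiff(names(points), c("fa", "fa_true", "replicate"))
  if (length(keys) == 0L) {
    synergyci_stop("no grouping columns left after dropping fa/replicate",
                   "schema_error")
  }
  agg <- stats::aggregate(points[["fa"]], by = points[keys],
                          FUN = mean)
  names(agg)[ncol(agg)] <- "fa"
  cnt <- stats::aggregate(points[["fa"]], by = points[keys], FUN = length)
  agg$n <- as.integer(cnt[[ncol(cnt)]])
  agg$fa <- pmin(pmax(agg$fa, 0), 1)
  ord <- do.call(order, agg[keys])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Read dose-response points from CSV
#'
#' Expects a header with columns `drug,dose,unit,fa` (dot decimal, UTF-8).
#'
#' @param path Path to the CSV file.
#' @return A data frame of dose-response points.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose", "unit", "fa")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    synergyci_stop(paste0("dose-response CSV is missing column(s): ",
                          paste(miss, collapse = ", ")), "schema_error")
  }
  df$dose <- as.numeric(df$dose)
  df$fa <- as.numeric(df$fa)
  df
}
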