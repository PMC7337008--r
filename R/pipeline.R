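# Pipeline and report assembly: ties viability -> median-effect fits ->
# fixed-ratio design -> CI table and Fa-CI curve into one reproducible run
# with a machine-readable manifest.

#' Build a validated run configuration
#'
#' Collects the knobs of the full synergy pipeline with every default made
#' explicit, so the emitted manifest completely determines a run.
#'
#' @param single Path to a dose-response CSV (`drug,dose,unit,fa`) covering
#'   every single drug, or an equivalent data frame.
#' @param combination Path to a combination CSV (one dose column per
#'   component plus `fa`, optionally `total_dose`), or a data frame.
#' @param unit Concentration-unit tag used when the inputs carry none.
#' @param dilution_factor Serial dilution factor of the fixed-ratio design.
#' @param n_levels Dose levels in the design ladder.
#' @param fa_grid Effect-level grid of the Fa-CI curve.
#' @param up,down Fold-change thresholds of the optional protein screen.
#' @param seed Integer seed recorded in the manifest (the deterministic
#'   pipeline itself draws no random numbers; the seed matters when inputs
#'   are simulated).
#' @param out_dir Output directory, created if missing.
#' @return A validated `synergy_run_config` list.
#' @export
synergy_run_config <- function(single, combination, unit = "uM",
                               dilution_factor = 1.5, n_levels = 6L,
                               fa_grid = seq(0.05, 0.95, by = 0.05),
                               up = 1.5, down = 0.67,
                               seed = 1L, out_dir = "synergy_out") {
  stopifnot_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) {
    synergyci_stop("`dilution_factor` must be > 1", "invalid_argument")
  }
  if (any(fa_grid <= 0) || any(fa_grid >= 1)) {
    synergyci_stop("`fa_grid` must lie strictly inside (0, 1)",
                   "out_of_domain")
  }
  structure(
    list(single = single, combination = combination, unit = unit,
         dilution_factor = dilution_factor, n_levels = as.integer(n_levels),
         fa_grid = fa_grid, up = up, down = down, seed = as.integer(seed),
         out_dir = out_dir),
    class = "synergy_run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

load_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full synergy pipeline
#'
#' Stages: (1) fit every single drug's median-effect curve; (2) derive the
#' Dm-proportional fixed-ratio design; (3) fit the mixture as a single
#' agent on total dose; (4) score each observed combination level with the
#' CI at its observed `fa` and classify it; (5) trace the Fa-CI curve on
#' the fitted combination curve. Emits, under `config$out_dir`:
#' `single_fits.csv`, `combination_fit.csv`, `ci_table.csv` (2-decimal
#' display) with `ci_table_full.csv` (full precision), `fa_ci_curve.csv`,
#' and `manifest.json` recording inputs, configuration, seed and package
#' version. Any stage error aborts the run and removes partial outputs.
#'
#' @param config A [synergy_run_config()].
#' @return Invisibly, a list with the fitted parameters, design, CI table,
#'   Fa-CI curve and output paths.
#' @export
run_synergy_pipeline <- function(config) {
  if (!inherits(config, "synergy_run_config")) {
    synergyci_stop("`config` must come from synergy_run_config()",
                   "invalid_argument")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c(single_fits = "single_fits.csv",
                       combination_fit = "combination_fit.csv",
                       ci_table = "ci_table.csv",
                       ci_table_full = "ci_table_full.csv",
                       fa_ci_curve = "fa_ci_curve.csv",
                       manifest = "manifest.json"))
  names(paths) <- c("single_fits", "combination_fit", "ci_table",
                    "ci_table_full", "fa_ci_curve", "manifest")
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)
    synergyci_stop(sprintf("stage `%s` failed: %s", stage,
                           conditionMessage(e)), "pipeline")
  }

  res <- list(paths = as.list(paths))

  # stage: single-drug fits
  single <- tryCatch({
    pts <- load_table(config$single, read_dose_response)
    drug_order <- unique(as.character(pts$drug))
    if ("replicate" %in% names(pts)) pts <- pool_replicates(pts)
    fits <- lapply(split(pts, pts$drug), fit_median_effect)
    fits[order(match(names(fits), drug_order))]
  }, error = function(e) on_fail("fit_single", e))
  log_stage("fit_single", "fitted %d single-drug curves", length(single))
  single_df <- do.call(rbind, lapply(single, function(p) {
    data.frame(drug = p$drug, dm = p$dm, m = p$m, r = p$r, unit = p$unit,
               n_used = p$n_used, stringsAsFactors = FALSE)
  }))
  rownames(single_df) <- NULL

  # stage: fixed-ratio design
  design <- tryCatch(
    design_fixed_ratio(single, dilution_factor = config$dilution_factor,
                       n_levels = config$n_levels),
    error = function(e) on_fail("design", e))
  log_stage("design", "weights %s",
            paste(sprintf("%.4f", design$weights), collapse = ":"))

  # stage: combination fit + CI table
  combo <- tryCatch({
    obs <- load_table(config$combination, read_combination)
    if ("replicate" %in% names(obs)) obs <- pool_replicates(obs)
    if (!"total_dose" %in% names(obs)) {
      comp_cols <- intersect(design$components, names(obs))
      if (length(comp_cols) != length(design$components)) {
        synergyci_stop(paste0(
          "combination table lacks `total_dose` and component columns: ",
          paste(setdiff(design$components, names(obs)), collapse = ", ")),
          "schema_error")
      }
      obs$total_dose <- rowSums(obs[, comp_cols, drop = FALSE])
    }
    for (j in seq_along(design$components)) {
      nm <- design$components[j]
      if (!nm %in% names(obs)) obs[[nm]] <- obs$total_dose * design$weights[j]
    }
    list(obs = obs,
         params = fit_combination_as_single(obs, unit = config$unit),
         table = ci_table(single, obs, components = design$components))
  }, error = function(e) on_fail("combination", e))
  log_stage("combination", "mixture Dm = %.4g %s, m = %.4g",
            combo$params$dm, combo$params$unit, combo$params$m)

  # stage: Fa-CI curve
  curve <- tryCatch(
    fa_ci_curve(single, combo$params, design, fa_grid = config$fa_grid),
    error = function(e) on_fail("fa_ci_curve", e))
  log_stage("fa_ci_curve", "%d grid points, CI range [%.3g, %.3g]",
            nrow(curve), min(curve$ci), max(curve$ci))

  # stage: write outputs
  tryCatch({
    utils::write.csv(single_df, paths["single_fits"], row.names = FALSE)
    written <- c(written, paths["single_fits"])
    combo_df <- data.frame(drug = "combination", dm = combo$params$dm,
                           m = combo$params$m, r = combo$params$r,
                           unit = combo$params$unit,
                           n_used = combo$params$n_used)
    utils::write.csv(combo_df, paths["combination_fit"], row.names = FALSE)
    written <- c(written, paths["combination_fit"])
    write_ci_table(combo$table, paths["ci_table"],
                   full_path = paths["ci_table_full"])
    written <- c(written, paths["ci_table"], paths["ci_table_full"])
    utils::write.csv(curve, paths["fa_ci_curve"], row.names = FALSE)
    written <- c(written, paths["fa_ci_curve"])
    manifest <- list(
      package = "synergyci",
      version = as.character(utils::packageVersion("synergyci")),
      config = list(
        single = if (is.character(config$single)) config$single else "<in-memory>",
        combination = if (is.character(config$combination)) config$combination else "<in-memory>",
        unit = config$unit, dilution_factor = config$dilution_factor,
        n_levels = config$n_levels, fa_grid = config$fa_grid,
        up = config$up, down = config$down, seed = config$seed),
      design = list(components = design$components,
                    weights = design$weights,
                    top_total_dose = design$top_total_dose))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, paths["manifest"])
  }, error = function(e) on_fail("write", e))
  log_stage("write", "outputs in %s", config$out_dir)

  res$single <- single
  res$single_table <- single_df
  res$design <- design
  res$combination <- combo$params
  res$ci_table <- combo$table
  res$fa_ci_curve <- curve
  invisible(res)
}

#' Write a CI table in report layout
#'
#' Columns: component doses, then `fa`, `ci`, `verdict`. The display file
#' rounds doses and CI to 2 decimals; a lossless full-precision companion
#' (suffix `_full` by default) allows exact round-trips.
#'
#' @param records A `ci_table` data frame from [ci_table()].
#' @param path Output CSV path (2-decimal display file).
#' @param full_path Companion full-precision CSV path; default derived from
#'   `path`.
#' @return `path`, invisibly.
#' @export
write_ci_table <- function(records, path,
                           full_path = sub("(\\.csv)?$", "_full.csv", path,
                                           ignore.case = TRUE)) {
  if (!is.data.frame(records)) {
    synergyci_stop("`records` must be a data frame", "invalid_argument")
  }
  df <- as.data.frame(records)
  num_cols <- setdiff(names(df), "verdict")
  utils::write.csv(df, full_path, row.names = FALSE)
  disp <- df
  for (nm in setdiff(num_cols, "fa")) {
    disp[[nm]] <- formatC(df[[nm]], format = "f", digits = 2)
  }
  utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
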