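# MTT plate processing: raw OD490 absorbances -> relative viability %,
# inhibition rate, and the fraction affected (fa) that feeds the
# median-effect fit.

#' Relative cell viability from OD490 absorbances
#'
#' `viability = (A_sample - A_blank) / (A_control - A_blank) * 100`.
#' The raw value may fall outside `[0, 100]` on noisy plates; truncation is
#' applied downstream (see [aggregate_replicates()]), not here.
#'
#' @param a_sample,a_control,a_blank OD490 absorbances (vectors recycle
#'   against each other).
#' @return Viability percentage(s), untruncated.
#' @examples
#' viability_percent(1.2, 2.0, 0.2) # 55.56 %
#' @export
viability_percent <- function(a_sample, a_control, a_blank) {
  if (any(!is.finite(a_sample)) || any(!is.finite(a_control)) ||
      any(!is.finite(a_blank))) {
    synergyci_stop("absorbances must be finite numbers", "invalid_argument")
  }
  if (any(a_control <= a_blank)) {
    synergyci_stop("control OD must exceed blank OD: no signal window",
                   "invalid_plate")
  }
  (a_sample - a_blank) / (a_control - a_blank) * 100
}

#' Inhibition rate from viability
#'
#' `100 - viability`, truncated to `[0, 100]`.
#'
#' @param viability Viability percentage(s).
#' @return Inhibition percentage(s) in `[0, 100]`.
#' @export
inhibition_rate <- function(viability) {
  if (!is.numeric(viability)) {
    synergyci_stop("`viability` must be numeric", "invalid_argument")
  }
  pmin(pmax(100 - viability, 0), 100)
}

#' Summarise replicate plate measurements into a viability table
#'
#' Takes long-format plate rows (`drug, dose, unit, replicate, role, od490`
#' with `role` one of `sample`, `control`, `blank`), pools the control and
#' blank wells by their mean OD, computes per-well viability with
#' [viability_percent()], and aggregates per `(drug, dose)` group:
#' mean viability, sample SD (`n - 1` denominator, 0 when `n = 1`), and n.
#' The mean viability is then truncated to `[0, 100]` (the raw mean is kept
#' in `viability_raw` for audit) and converted to inhibition
#' (`100 - viability`) and fraction affected (`fa = 1 - viability/100`).
#'
#' Controls and blanks are pooled across the whole input (one plate group
#' per call); process plates separately if their signal windows differ.
#'
#' @param rows Data frame of plate measurements.
#' @return A data frame of class `viability_table` with columns `drug,
#'   dose, unit, n, viability_raw, viability, sd, inhibition, fa`.
#' @examples
#' rows <- data.frame(
#'   drug = c("A", "A", NA, NA), dose = c(5, 5, NA, NA), unit = "uM",
#'   replicate = c(1, 2, 1, 1), role = c("sample", "sample", "control", "blank"),
#'   od490 = c(1.1, 1.3, 2.0, 0.2))
#' aggregate_replicates(rows)
#' @export
aggregate_replicates <- function(rows) {
  need <- c("drug", "dose", "unit", "replicate", "role", "od490")
  if (!is.data.frame(rows) || !all(need %in% names(rows))) {
    synergyci_stop(paste0("plate table must have columns: ",
                          paste(need, collapse = ", ")), "schema_error")
  }
  role <- as.character(rows$role)
  bad <- setdiff(unique(role), c("sample", "control", "blank"))
  if (length(bad)) {
    synergyci_stop(paste0("unknown role(s): ", paste(bad, collapse = ", ")),
                   "schema_error")
  }
  od <- as.numeric(rows$od490)
  if (any(!is.finite(od)) || any(od < 0)) {
    synergyci_stop("od490 must be non-negative and finite", "invalid_argument")
  }
  if (!any(role == "control") || !any(role == "blank")) {
    synergyci_stop("plate group needs at least one control and one blank row",
                   "invalid_plate")
  }
  a_control <- mean(od[role == "control"])
  a_blank <- mean(od[role == "blank"])

  smp <- rows[role == "sample", , drop = FALSE]
  if (nrow(smp) == 0L) {
    synergyci_stop("no sample rows in plate table", "invalid_plate")
  }
  viab <- viability_percent(as.numeric(smp$od490), a_control, a_blank)

  key <- interaction(smp$drug, smp$dose, drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(seq_along(viab), key), function(idx) {
    v <- viab[idx]
    data.frame(
      drug = as.character(smp$drug[idx[1]]),
      dose = as.numeric(smp$dose[idx[1]]),
      unit = as.character(smp$unit[idx[1]]),
      n = length(v),
      viability_raw = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$drug, out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out$viability <- pmin(pmax(out$viability_raw, 0), 100)
  out$inhibition <- 100 - out$viability
  out$fa <- 1 - out$viability / 100
  class(out) <- c("viability_table", class(out))
  out
}

#' Read plate measurements from CSV
#'
#' Columns: `drug,dose,unit,replicate,role,od490` (header required).
#'
#' @param path Path to the CSV file.
#' @return Data frame of plate measurements.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose", "unit", "replicate", "role", "od490")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    synergyci_stop(paste0("plate CSV is missing column(s): ",
                          paste(miss, collapse = ", ")), "schema_error")
  }
  df
}

#' Write a viability table to CSV
#'
#' @param table A `viability_table` from [aggregate_replicates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
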