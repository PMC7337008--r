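# Classed conditions so callers and tests can discriminate failure modes
# without matching on message text.

synergyci_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(paste0("synergyci_", class), "synergyci_error"),
                      call = call))
}

synergyci_warn <- function(message, class) {
  warning(warningCondition(message,
                           class = c(paste0("synergyci_", class),
                                     "synergyci_warning")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    synergyci_stop(sprintf("`%s` must be a single finite number", name),
                   "invalid_argument")
  }
  if (positive && x <= 0) {
    synergyci_stop(sprintf("`%s` must be > 0 (got %g)", name, x),
                   "invalid_argument")
  }
  invisible(x)
}
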