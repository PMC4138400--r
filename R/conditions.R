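# Structured error conditions so callers can catch failure modes by class.

gs_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "gripscore_error")))
}

gs_check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gs_abort(sprintf("`%s` must be a single finite number", name),
             "gs_invalid_parameter")
  }
  if (positive && x <= 0) {
    gs_abort(sprintf("`%s` must be > 0 (got %g)", name, x),
             "gs_invalid_parameter")
  }
  invisible(x)
}
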