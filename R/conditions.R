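# Classed conditions so callers can distinguish failure modes programmatically.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cbhkin_error")))
}

abort_invalid      <- function(msg) abort(msg, "cbhkin_invalid_parameter")
abort_consistency  <- function(msg) abort(msg, "cbhkin_consistency_error")
abort_fit          <- function(msg) abort(msg, "cbhkin_fit_failure")
abort_empty        <- function(msg) abort(msg, "cbhkin_empty_dataset")
abort_insufficient <- function(msg) abort(msg, "cbhkin_insufficient_data")
abort_incomplete   <- function(msg) abort(msg, "cbhkin_incomplete_input")
abort_parse        <- function(msg) abort(msg, "cbhkin_parse_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_invalid(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    abort_invalid(sprintf("`%s` must be a single non-negative finite number", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    abort_invalid(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

check_fraction <- function(x, name, open_left = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || x > 1)
    abort_invalid(sprintf("`%s` must be a fraction in %s0, 1]",
                          name, if (open_left) "(" else "["))
  invisible(x)
}
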