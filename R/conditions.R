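# Classed conditions so callers (and the CLI) can map failures to exit codes.

stop_cardiosim <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cardiosim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_invalid_config <- function(msg, ...) {
  stop_cardiosim("cardiosim_invalid_config", msg, ...)
}

abort_invalid_input <- function(msg, ...) {
  stop_cardiosim("cardiosim_invalid_input", msg, ...)
}

abort_numerical <- function(msg, ...) {
  stop_cardiosim("cardiosim_numerical_failure", msg, ...)
}

abort_fit_failure <- function(msg, ...) {
  stop_cardiosim("cardiosim_fit_failure", msg, ...)
}

abort_io <- function(msg, ...) {
  stop_cardiosim("cardiosim_io_error", msg, ...)
}

abort_insufficient_data <- function(msg, ...) {
  stop_cardiosim("cardiosim_insufficient_data", msg, ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         abort = abort_invalid_config) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    abort("`%s` = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}
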