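# Structured error conditions. Three families mirror the failure surface of
# the tool: bad parameter values, missing keys/columns, and I/O/format
# problems. Tests and the CLI dispatch on the condition class.

stop_value_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("spotscreen_value_error", "spotscreen_error")))
}

stop_key_error <- function(msg) {
  stop(errorCondition(msg, class = c("spotscreen_key_error", "spotscreen_error")))
}

stop_io_error <- function(msg) {
  stop(errorCondition(msg, class = c("spotscreen_io_error", "spotscreen_error")))
}

# match.arg analogue that raises a value error instead of a plain error
match_direction <- function(direction) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% c("lower", "higher", "both")) {
    stop_value_error(sprintf(
      "`direction` must be one of 'lower', 'higher', 'both' (got %s)",
      deparse(direction)[1L]))
  }
  direction
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop_value_error(sprintf("`%s` must be a finite number %s %s (got %s)",
                             name, if (strict) ">" else ">=", format(lower),
                             deparse(x)[1L]))
  }
  x
}
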