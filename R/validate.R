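# Classed error conditions so callers (and the CLI) can distinguish
# bad user input from programming errors.

stop_validation <- function(msg, field = NULL, call. = FALSE) {
  cond <- structure(
    class = c("cascade_validation_error", "error", "condition"),
    list(message = msg, call = NULL, field = field)
  )
  stop(cond)
}

stop_config <- function(msg, field = NULL) {
  cond <- structure(
    class = c("cascade_config_error", "cascade_validation_error",
              "error", "condition"),
    list(message = msg, call = NULL, field = field)
  )
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

check_proportion <- function(x, field) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    stop_validation(
      sprintf("`%s` must be a single number in [0, 1], got %s",
              field, deparse1(x)),
      field = field
    )
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is_scalar_number(x) || x < 0) {
    stop_validation(
      sprintf("`%s` must be a single non-negative number, got %s",
              field, deparse1(x)),
      field = field
    )
  }
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_validation(
      sprintf("`%s` must be a single positive number, got %s",
              field, deparse1(x)),
      field = field
    )
  }
  invisible(x)
}

check_string <- function(x, field, allow_empty = FALSE) {
  if (!is_scalar_string(x) || (!allow_empty && !nzchar(x))) {
    stop_validation(
      sprintf("`%s` must be a non-empty string", field),
      field = field
    )
  }
  invisible(x)
}
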