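#' Display rounding with ties away from zero
#'
#' Internal model flows are expected values and therefore fractional;
#' published tables print integers and whole or 2-decimal currency.
#' This is the single rounding routine used for every displayed number.
#' Halves round away from zero (76.5 -> 77, 94.5 -> 95), unlike base
#' [round()], which rounds halves to even. `NA`/`NaN` inputs propagate
#' unchanged so undefined metrics stay visibly undefined.
#'
#' @param value Numeric vector of unrounded values.
#' @param kind One of `"count"` (nearest integer), `"currency_whole"`
#'   (nearest whole currency unit), `"currency_cents"` (2 decimal places).
#' @return Numeric vector of rounded values; `NA` where `value` is
#'   `NA`/`NaN`.
#' @examples
#' display_round(367.5, "count")          # 368
#' display_round(76.5, "count")           # 77 (not banker's 76)
#' display_round(242.857142, "currency_cents")  # 242.86
#' @export
display_round <- function(value,
                          kind = c("count", "currency_whole", "currency_cents")) {
  kind <- match.arg(kind)
  if (!is.numeric(value)) {
    stop_validation("`value` must be numeric", field = "value")
  }
  digits <- if (kind == "currency_cents") 2L else 0L
  round_half_away(value, digits)
}

round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5) / p
  out[is.na(x)] <- NA_real_
  out
}
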