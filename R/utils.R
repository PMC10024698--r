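#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (`round_half_up(0.5) == 1`),
#' matching how disproportionality results are conventionally printed, unlike
#' base [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
pv_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "pvsignal_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_format <- function(message) pv_stop(message, "pvsignal_format_error")

stop_record <- function(message, rows = integer()) {
  pv_stop(message, "pvsignal_record_error", rows = rows)
}

stop_undefined <- function(what, cell = NULL) {
  msg <- if (is.null(cell)) {
    sprintf("%s is undefined for this table", what)
  } else {
    sprintf("%s is undefined: cell '%s' makes a denominator zero", what, cell)
  }
  pv_stop(msg, "pvsignal_undefined_statistic", cell = cell)
}

stop_config <- function(message) pv_stop(message, "pvsignal_config_error")

stop_usage <- function(message) pv_stop(message, "pvsignal_usage_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

#' @noRd
check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_config(sprintf("%s must be probabilities in [0, 1]", what))
  }
  invisible(p)
}

#' @noRd
check_distribution <- function(p, what, tol = 1e-8) {
  check_prob_vector(p, what)
  if (abs(sum(p) - 1) > tol) {
    stop_config(sprintf("%s must sum to 1 (got %.6f)", what, sum(p)))
  }
  invisible(p)
}
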