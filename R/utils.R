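# internal validation helpers shared across modules

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single numeric value")
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) stop_field(field, sprintf("must lie in %s0, 1%s, got %g",
                                                  if (allow_zero) "[" else "(",
                                                  if (allow_one) "]" else ")", x))
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single numeric value")
  }
  if (if (strict) x <= 0 else x < 0) {
    stop_field(field, sprintf("must be %s, got %g", if (strict) "positive" else "non-negative", x))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation (`stats::quantile()` type 7) throughout
#' the package; this is the single place the convention is set.
#'
#' @param x numeric vector.
#' @return named numeric vector with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# days per model year, used wherever rates are annualized
DAYS_PER_YEAR <- 365.25
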