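#' Hour intervals
#'
#' Uncertainty in Pain-Track durations and derived discomfort hours is carried
#' as closed intervals `[lo, hi]`. Bounds are treated as jointly attained:
#' scaling and addition combine lo with lo and hi with hi, which is the
#' convention needed to reproduce published cumulative-pain tables from their
#' phase tables. Subtraction of costs from revenues (economics) is the usual
#' anti-tone interval subtraction and has its own helper.
#'
#' @param lo,hi numeric bounds, `0 <= lo <= hi` for hour intervals.
#' @return an object of class `hour_interval` (numeric length 2).
#' @examples
#' iv(2, 3.2)
#' iv_add(iv(1, 2), iv(0.5, 1))
#' iv_scale(iv(2, 3), 0.1)
#' @export
iv <- function(lo, hi = lo) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (is.na(lo) || is.na(hi) || lo > hi) {
    stop("invalid interval: lo must be <= hi and finite, got [", lo, ", ", hi, "]")
  }
  structure(c(lo = lo, hi = hi), class = "hour_interval")
}

#' @rdname iv
#' @param x an object to coerce/test.
#' @export
is_iv <- function(x) inherits(x, "hour_interval")

#' @rdname iv
#' @export
as_iv <- function(x) {
  if (is_iv(x)) return(x)
  stopifnot(is.numeric(x), length(x) %in% c(1L, 2L))
  if (length(x) == 1L) iv(x, x) else iv(x[[1L]], x[[2L]])
}

#' @rdname iv
#' @param a,b intervals (or numerics coercible to intervals).
#' @export
iv_add <- function(a, b) {
  a <- as_iv(a); b <- as_iv(b)
  iv(a[["lo"]] + b[["lo"]], a[["hi"]] + b[["hi"]])
}

#' @rdname iv
#' @param k a non-negative scalar multiplier.
#' @export
iv_scale <- function(a, k) {
  a <- as_iv(a)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  iv(a[["lo"]] * k, a[["hi"]] * k)
}

#' @rdname iv
#' @details `iv_sub_antitone(a, b)` returns `[a_lo - b_hi, a_hi - b_lo]`,
#'   the standard interval difference used for net = revenue - cost.
#' @export
iv_sub_antitone <- function(a, b) {
  a <- as_iv(a); b <- as_iv(b)
  iv(a[["lo"]] - b[["hi"]], a[["hi"]] - b[["lo"]])
}

#' @rdname iv
#' @export
iv_mid <- function(a) {
  a <- as_iv(a)
  (a[["lo"]] + a[["hi"]]) / 2
}

#' @rdname iv
#' @export
iv_lo <- function(a) as_iv(a)[["lo"]]

#' @rdname iv
#' @export
iv_hi <- function(a) as_iv(a)[["hi"]]

#' @export
print.hour_interval <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x[["lo"]], x[["hi"]]))
  invisible(x)
}

#' @export
format.hour_interval <- function(x, digits = 3, ...) {
  sprintf("[%s, %s]", format(x[["lo"]], digits = digits),
          format(x[["hi"]], digits = digits))
}
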