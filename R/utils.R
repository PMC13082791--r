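# Internal numerical helpers.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Trapezoidal integration on a grid
#'
#' @param x strictly increasing grid.
#' @param y values on the grid.
#' @return the trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Uniform grid over [lo, hi] with n nodes plus the trapezoid weights.
trapz_grid <- function(lo, hi, n) {
  xs <- seq(lo, hi, length.out = n)
  h <- (hi - lo) / (n - 1)
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  list(x = xs, w = w)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
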