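#' Uniform integer stimulus prior
#'
#' A condition of either task is defined by the uniform distribution over
#' the integers of a range. The width of the range is the context
#' variable whose effect on behavioral imprecision the package studies.
#'
#' @param x_min,x_max integer bounds of the range, `x_min < x_max`.
#' @param label optional condition label (e.g. `"Narrow"`).
#' @return an object of class `prior_spec` with fields `x_min`, `x_max`,
#'   `width` (`x_max - x_min`), `midpoint`, `support` (the integer grid)
#'   and `label`.
#' @examples
#' prior_spec(50, 70, "Narrow")
#' @export
prior_spec <- function(x_min, x_max, label = NULL) {
  stopifnot_scalar(x_min, "x_min")
  stopifnot_scalar(x_max, "x_max")
  if (x_min != round(x_min) || x_max != round(x_max))
    stop("prior bounds must be integers", call. = FALSE)
  if (x_min >= x_max)
    stop("'x_min' must be strictly smaller than 'x_max'", call. = FALSE)
  structure(
    list(
      x_min = as.integer(x_min),
      x_max = as.integer(x_max),
      width = as.integer(x_max - x_min),
      midpoint = (x_min + x_max) / 2,
      support = as.integer(x_min):as.integer(x_max),
      label = label
    ),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Uniform integer prior%s: [%d, %d]  (width %d, midpoint %.1f)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$x_min, x$x_max, x$width, x$midpoint))
  invisible(x)
}

#' Standard condition sets of the two numerosity tasks
#'
#' The estimation task uses three priors with a common midpoint of 60 and
#' widths 20, 40 and 60; the discrimination task uses two priors with
#' midpoint 50 and widths 30 and 80.
#'
#' @return a named list of [prior_spec()] objects.
#' @examples
#' estimation_priors()$Medium
#' @export
estimation_priors <- function() {
  list(
    Narrow = prior_spec(50, 70, "Narrow"),
    Medium = prior_spec(40, 80, "Medium"),
    Wide   = prior_spec(30, 90, "Wide")
  )
}

#' @rdname estimation_priors
#' @export
discrimination_priors <- function() {
  list(
    Narrow = prior_spec(35, 65, "Narrow"),
    Wide   = prior_spec(10, 90, "Wide")
  )
}
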