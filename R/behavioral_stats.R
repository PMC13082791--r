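# Descriptive battery for the two tasks: binned excursion variances,
# scaling diagnostics, psychometric summaries and the standard tests.

#' Five-bin partition of a condition's prior range
#'
#' The standard partitions used when pooling estimation responses: the
#' third bin is centered on the prior midpoint (60) and the second to
#' fourth bins have equal length; the outer bins take the remaining
#' integers.
#'
#' @param condition `"Narrow"`, `"Medium"` or `"Wide"`.
#' @return an object of class `bin_scheme`: a list with `condition` and
#'   `ranges`, a 5 x 2 matrix of inclusive integer bounds.
#' @examples
#' default_bins("Narrow")$ranges
#' @export
default_bins <- function(condition = c("Narrow", "Medium", "Wide")) {
  condition <- match.arg(condition)
  ranges <- switch(condition,
    Narrow = rbind(c(50, 52), c(53, 57), c(58, 62), c(63, 67), c(68, 70)),
    Medium = rbind(c(40, 46), c(47, 55), c(56, 64), c(65, 73), c(74, 80)),
    Wide   = rbind(c(30, 40), c(41, 53), c(54, 66), c(67, 79), c(80, 90)))
  structure(list(condition = condition, ranges = ranges),
            class = "bin_scheme")
}

bin_of <- function(x, bins) {
  findInterval(x, c(bins$ranges[, 1L], bins$ranges[5L, 2L] + 1L))
}

#' Excursion variance per bin
#'
#' Isolates trial-to-trial variability from stimulus heterogeneity
#' within a bin: from each estimate the mean estimate for the same
#' presented number is subtracted, and the variance of these excursions
#' is computed per bin. Numbers presented a single time contribute a
#' zero excursion and are flagged.
#'
#' @param table estimation rows of a single condition (`x`, `response`).
#' @param bins a [bin_scheme()] for the condition.
#' @param ddof variance denominator offset: 1 for the sample variance
#'   (default), 0 for the population variance.
#' @return a `data.frame` with one row per bin: `bin`, `lo`, `hi`, `n`,
#'   `variance` (NA for an empty bin), `n_single` (numbers with one
#'   trial).
#' @examples
#' tab <- data.frame(x = c(60, 60), response = c(58, 62))
#' excursion_variance(tab, default_bins("Narrow"), ddof = 0)$variance[3]
#' @export
excursion_variance <- function(table, bins, ddof = 1) {
  stopifnot(inherits(bins, "bin_scheme"))
  mean_by_x <- tapply(table$response, table$x, mean)
  exc <- table$response - mean_by_x[as.character(table$x)]
  b <- bin_of(table$x, bins)
  n_by_x <- table(table$x)
  singles <- names(n_by_x)[n_by_x == 1L]
  out <- data.frame(bin = 1:5, lo = bins$ranges[, 1L],
                    hi = bins$ranges[, 2L], n = NA_integer_,
                    variance = NA_real_, n_single = NA_integer_)
  for (i in 1:5) {
    e <- exc[b == i]
    out$n[i] <- length(e)
    out$n_single[i] <- sum(as.integer(singles) >= out$lo[i] &
                             as.integer(singles) <= out$hi[i])
    if (length(e) >= 2L)
      out$variance[i] <- sum((e - mean(e))^2) / (length(e) - ddof)
  }
  out
}

#' Coefficient of variation per presented number
#'
#' The ratio of the standard deviation of estimates to the mean
#' estimate, for each presented number with at least two trials.
#' Constancy of this curve is the signature of scalar variability; a
#' decreasing curve speaks against it.
#'
#' @param table estimation rows of a single condition.
#' @param ddof variance denominator offset (1 sample, 0 population).
#' @return a `data.frame` with `x`, `n`, `mean`, `sd`, `cv`.
#' @export
cv_curve <- function(table, ddof = 1) {
  sp <- split(table$response, table$x)
  sp <- sp[lengths(sp) >= 2L]
  out <- data.frame(
    x = as.integer(names(sp)),
    n = lengths(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v)
      sqrt(sum((v - mean(v))^2) / (length(v) - ddof)), numeric(1)))
  if (any(out$mean == 0)) stop("zero mean estimate", call. = FALSE)
  out$cv <- out$sd / out$mean
  rownames(out) <- NULL
  out
}

#' Absolute and relative estimation error
#'
#' @param table estimation rows of a single condition.
#' @param w the condition's prior width.
#' @return list with `mean_abs_error` and `ratio` (error over width).
#' @examples
#' relative_error(data.frame(x = 60, response = 66), w = 20)
#' @export
relative_error <- function(table, w) {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  m <- mean(abs(table$response - table$x))
  list(mean_abs_error = m, ratio = m / w)
}

#' Two-point affine extrapolation of response variance
#'
#' Fits `variance = intercept + slope * t(w)` through two observed
#' (width, variance) points, with the abscissa transform `t` either the
#' width itself or its square, and evaluates the line at a target
#' width. Contrasting the two transforms' predictions against the
#' observed wide-condition variance is the key diagnostic separating
#' square-root scaling of the imprecision from range normalization.
#'
#' @param points a 2-row matrix or data frame of `(w, variance)` pairs.
#' @param transform `"width"` or `"width_squared"`.
#' @param target_w width at which to predict.
#' @return the predicted variance.
#' @examples
#' affine_extrapolate(rbind(c(20, 17.64), c(40, 46.24)),
#'                    "width_squared", 60)  # 93.91
#' @export
affine_extrapolate <- function(points, transform = c("width",
                                                     "width_squared"),
                               target_w) {
  transform <- match.arg(transform)
  points <- as.matrix(points)
  if (nrow(points) != 2L)
    stop("exactly two (w, variance) points required", call. = FALSE)
  t_of <- function(w) if (transform == "width") w else w^2
  tw <- t_of(points[, 1L])
  if (tw[1L] == tw[2L])
    stop("coincident transformed abscissae", call. = FALSE)
  slope <- (points[2L, 2L] - points[1L, 2L]) / (tw[2L] - tw[1L])
  intercept <- points[1L, 2L] - slope * tw[1L]
  intercept + slope * t_of(target_w)
}

#' Binned psychometric summaries
#'
#' Proportions of "red" choices against the signed average difference,
#' and of correct choices against the absolute difference normalized by
#' `w^alpha`, in equal-count quantile bins, with binomial 95% confidence
#' intervals (normal approximation).
#'
#' @param table discrimination trial rows (may span conditions).
#' @param normalizer_alpha exponent used to normalize the abscissa of
#'   the correct-choice curve.
#' @param n_bins number of quantile bins.
#' @param priors optional condition priors.
#' @return a list with `signed` and `correct` data frames (one row per
#'   condition x bin: abscissa midpoint, `n`, `prop`, `lo`, `hi`).
#' @export
psychometric_bins <- function(table, normalizer_alpha = 0.75,
                              n_bins = 8, priors = NULL) {
  priors <- table_priors(table, priors, task = "discrimination")
  ci <- function(p, n) {
    se <- sqrt(pmax(p * (1 - p), 0) / pmax(n, 1))
    list(lo = pmax(0, p - 1.96 * se), hi = pmin(1, p + 1.96 * se))
  }
  bin_summary <- function(z, y) {
    br <- unique(stats::quantile(z, probs = seq(0, 1, length.out =
                                                  n_bins + 1L)))
    if (length(br) < 2L) br <- range(z) + c(-0.5, 0.5)
    g <- cut(z, br, include.lowest = TRUE)
    n <- tapply(y, g, length)
    p <- tapply(y, g, mean)
    mid <- tapply(z, g, mean)
    keep <- !is.na(n)
    b <- ci(p[keep], n[keep])
    data.frame(abscissa = as.numeric(mid[keep]),
               n = as.integer(n[keep]), prop = as.numeric(p[keep]),
               lo = b$lo, hi = b$hi)
  }
  signed <- list()
  correct <- list()
  for (cn in unique(table$condition)) {
    sub <- table[table$condition == cn, ]
    w <- priors[[cn]]$width
    d <- sub$x_R - sub$x_B
    red <- sub$choice == "red"
    ok <- ifelse(d >= 0, red, !red)   # correct = chose larger average
    s1 <- bin_summary(d, red)
    s1$condition <- cn
    nz <- d != 0
    s2 <- bin_summary(abs(d[nz]) / w^normalizer_alpha, ok[nz])
    s2$condition <- cn
    signed[[cn]] <- s1
    correct[[cn]] <- s2
  }
  list(signed = do.call(rbind, signed),
       correct = do.call(rbind, correct))
}

#' Psychometric collapse across conditions
#'
#' How well the correct-choice curves of the two conditions align when
#' the abscissa is normalized by `w^alpha`: the maximum binwise gap
#' between the two conditions' proportions on shared quantile bins of
#' the normalized abscissa. The exponent that produces the smallest gap
#' is the one under which behavior is condition-invariant.
#'
#' @param table discrimination trial rows spanning two conditions.
#' @param alphas candidate exponents.
#' @param n_bins shared quantile bins.
#' @param priors optional condition priors.
#' @return a named numeric vector of maximal gaps, one per exponent.
#' @export
psychometric_collapse <- function(table, alphas = c(0.5, 0.75, 1),
                                  n_bins = 6, priors = NULL) {
  priors <- table_priors(table, priors, task = "discrimination")
  conds <- unique(table$condition)
  if (length(conds) != 2L) stop("need exactly two conditions",
                                call. = FALSE)
  out <- vapply(alphas, function(a) {
    d <- table$x_R - table$x_B
    red <- table$choice == "red"
    ok <- ifelse(d >= 0, red, !red)
    w <- vapply(table$condition,
                function(cn) priors[[cn]]$width, numeric(1))
    z <- abs(d) / w^a
    nz <- d != 0
    z <- z[nz]; ok <- ok[nz]; cond <- table$condition[nz]
    br <- unique(stats::quantile(z, seq(0, 1, length.out = n_bins + 1L)))
    g <- cut(z, br, include.lowest = TRUE)
    p1 <- tapply(ok[cond == conds[1L]], g[cond == conds[1L]], mean)
    p2 <- tapply(ok[cond == conds[2L]], g[cond == conds[2L]], mean)
    max(abs(p1 - p2), na.rm = TRUE)
  }, numeric(1))
  names(out) <- paste0("alpha=", alphas)
  out
}

#' Classical tests used by the descriptive battery
#'
#' `levene_test` runs the mean-centered Levene test of equality of
#' variances (`center = median` gives the Brown-Forsythe variant);
#' `fisher_exact_2x2` the exact two-sided test on a 2x2 count table;
#' `holm_adjust` the Bonferroni-Holm step-down adjustment.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return `levene_test`: list with `W` and `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  centerfun <- if (center == "mean") mean else stats::median
  lt <- car::leveneTest(values, groups, center = centerfun)
  list(W = lt[1L, "F value"], p = lt[1L, "Pr(>F)"])
}

#' @rdname levene_test
#' @param counts a 2x2 matrix of counts.
#' @return `fisher_exact_2x2`: list with odds ratio `OR` and `p`.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("need a 2x2 table", call. = FALSE)
  ft <- stats::fisher.test(counts)
  list(OR = unname(ft$estimate), p = ft$p.value)
}

#' @rdname levene_test
#' @param pvals numeric vector of p-values.
#' @return `holm_adjust`: the adjusted p-values.
#' @export
holm_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "holm")
}

#' First-half versus second-half stability summaries
#'
#' Splits a table on its `half` column and compares the halves:
#' for estimation tables, per-bin excursion variances with Levene tests
#' of equality across halves (Holm-adjusted over bins); for
#' discrimination tables, binned choice proportions with Fisher exact
#' tests per bin (Holm-adjusted).
#'
#' @param table a trial table with a `half` column.
#' @param task `"estimation"` or `"discrimination"`.
#' @param priors optional condition priors.
#' @return a list per condition with the half summaries and the
#'   adjusted p-values.
#' @export
half_split <- function(table, task = c("estimation", "discrimination"),
                       priors = NULL) {
  task <- match.arg(task)
  if (!"half" %in% names(table))
    stop("'half' column missing", call. = FALSE)
  priors <- table_priors(table, priors, task = task)
  out <- list()
  for (cn in unique(table$condition)) {
    sub <- table[table$condition == cn, ]
    h1 <- sub[sub$half == "first", ]
    h2 <- sub[sub$half == "second", ]
    if (task == "estimation") {
      bins <- default_bins(cn)
      v1 <- excursion_variance(h1, bins)
      v2 <- excursion_variance(h2, bins)
      pv <- vapply(1:5, function(i) {
        sel1 <- bin_of(h1$x, bins) == i
        sel2 <- bin_of(h2$x, bins) == i
        e1 <- h1$response[sel1] -
          tapply(h1$response, h1$x, mean)[as.character(h1$x[sel1])]
        e2 <- h2$response[sel2] -
          tapply(h2$response, h2$x, mean)[as.character(h2$x[sel2])]
        if (length(e1) < 2L || length(e2) < 2L) return(NA_real_)
        levene_test(c(e1, e2), rep(c("first", "second"),
                                   c(length(e1), length(e2))))$p
      }, numeric(1))
      out[[cn]] <- list(first = v1, second = v2,
                        p_holm = holm_adjust(pv[!is.na(pv)]))
    } else {
      d <- sub$x_R - sub$x_B
      br <- unique(stats::quantile(d, seq(0, 1, length.out = 7L)))
      g <- cut(d, br, include.lowest = TRUE)
      pv <- vapply(levels(g), function(lv) {
        n1 <- sum(g == lv & sub$half == "first")
        n2 <- sum(g == lv & sub$half == "second")
        r1 <- sum(g == lv & sub$half == "first" & sub$choice == "red")
        r2 <- sum(g == lv & sub$half == "second" & sub$choice == "red")
        if (n1 == 0 || n2 == 0) return(NA_real_)
        fisher_exact_2x2(rbind(c(r1, n1 - r1), c(r2, n2 - r2)))$p
      }, numeric(1))
      out[[cn]] <- list(
        first = mean(sub$choice[sub$half == "first"] == "red"),
        second = mean(sub$choice[sub$half == "second"] == "red"),
        p_holm = holm_adjust(pv[!is.na(pv)]))
    }
  }
  out
}
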