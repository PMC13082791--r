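# The Gaussian encoding / Bayesian-mean decoding observer.
#
# A numerosity x elicits a noisy internal representation
#   r | x ~ N(mu(x), (nu * w^alpha)^2),
# where mu is the encoding function (identity or natural log), nu is the
# baseline imprecision, w the prior width and alpha the width-scaling
# exponent.  Estimation responses add a truncated, rounded motor stage;
# discrimination choices compare two independent representations.

#' Encoding specification
#'
#' @param kind `"linear"` (identity transducer) or `"logarithmic"`
#'   (natural log, a compressed number line).
#' @param nu baseline imprecision (standard deviation of the
#'   representation at unit prior width), `>= 0`. A value of 0 builds the
#'   deliberate no-cognitive-noise variant.
#' @param alpha width-scaling exponent, `>= 0`. The representation's
#'   standard deviation is `nu * w^alpha`.
#' @return an object of class `encoding_spec`.
#' @examples
#' encoding_spec("linear", nu = 1, alpha = 0.5)
#' @export
encoding_spec <- function(kind = c("linear", "logarithmic"), nu, alpha) {
  kind <- match.arg(kind)
  stopifnot_scalar(nu, "nu")
  stopifnot_scalar(alpha, "alpha")
  if (nu < 0) stop("'nu' must be >= 0", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  structure(list(kind = kind, nu = nu, alpha = alpha),
            class = "encoding_spec")
}

#' Encoding transducer
#'
#' The mean of the internal representation as a function of the stimulus:
#' identity for the linear encoding, natural log for the logarithmic one.
#'
#' @param x stimulus magnitude(s); must be `> 0` for the logarithmic kind.
#' @param kind `"linear"` or `"logarithmic"`.
#' @return `mu(x)`, vectorized over `x`.
#' @examples
#' mu(60, "linear")
#' mu(exp(1), "logarithmic")
#' @export
mu <- function(x, kind = c("linear", "logarithmic")) {
  kind <- match.arg(kind)
  if (kind == "linear") return(as.numeric(x))
  if (any(x <= 0)) stop("logarithmic encoding requires x > 0", call. = FALSE)
  log(x)
}

# Derivative of the transducer.
mu_prime <- function(x, kind) {
  if (kind == "linear") rep(1, length(x)) else 1 / x
}

# Representation sd nu * w^alpha for a given prior width.
encoding_sd <- function(enc, w) enc$nu * w^enc$alpha

#' Fisher information of the encoding
#'
#' For the Gaussian representation the Fisher information about the
#' stimulus is `(mu'(x) / (nu * w^alpha))^2`: the squared local slope of
#' the transducer over the representation variance. Its inverse square
#' root is the local scale of representational imprecision.
#'
#' @param x stimulus magnitude(s).
#' @param enc an [encoding_spec()]; `nu` must be strictly positive.
#' @param w prior width, `> 0`.
#' @return Fisher information, vectorized over `x`.
#' @examples
#' fisher_information(60, encoding_spec("linear", 1, 0.5), w = 20)  # 0.05
#' @export
fisher_information <- function(x, enc, w) {
  stopifnot(inherits(enc, "encoding_spec"))
  stopifnot_scalar(w, "w", positive = TRUE)
  if (enc$nu == 0)
    stop("Fisher information is undefined for nu = 0 (infinite precision)",
         call. = FALSE)
  (mu_prime(x, enc$kind) / encoding_sd(enc, w))^2
}

#' Bayesian posterior-mean readout
#'
#' Given a representation value `r`, the observer decodes the mean of the
#' posterior over the integers of the prior range,
#' `x*(r) = E[x | r]`, with the discrete uniform prior and the Gaussian
#' encoding likelihood. Weights are accumulated in log space so the
#' readout never produces NaN, even far in the tails where it saturates
#' at the prior bounds.
#'
#' @param r representation value(s).
#' @param enc an [encoding_spec()] with `nu > 0`.
#' @param prior a [prior_spec()].
#' @return the posterior mean, vectorized over `r`; strictly increasing
#'   in `r` and confined to `[x_min, x_max]`.
#' @examples
#' p <- prior_spec(50, 70)
#' posterior_mean(60, encoding_spec("linear", 1, 0.5), p)
#' @export
posterior_mean <- function(r, enc, prior) {
  stopifnot(inherits(enc, "encoding_spec"), inherits(prior, "prior_spec"))
  s <- encoding_sd(enc, prior$width)
  if (s <= 0) stop("posterior_mean requires nu > 0", call. = FALSE)
  xs <- prior$support
  mus <- mu(xs, enc$kind)
  # log-weights: n_r x n_support
  lw <- -0.5 * (outer(r, mus, "-") / s)^2
  lw <- lw - apply(lw, 1L, max)
  w <- exp(lw)
  as.numeric((w %*% xs) / rowSums(w))
}

# Motor-stage kernel: probability that the recorded integer response is
# xhat, for a truncated normal (mean center, sd sigma0, bounds of the
# prior) whose draws are rounded to the nearest in-range integer. The
# boundary rounding cells are [x_min, x_min + 1/2] and [x_max - 1/2,
# x_max]; with the truncation they absorb all tail mass, so each row sums
# to one.  Returns a length(centers) x length(support) matrix.
motor_kernel <- function(centers, sigma0, prior) {
  xs <- prior$support
  n <- length(xs)
  edges <- c(xs[1L], xs[-n] + 0.5, xs[n])
  if (sigma0 <= 0) {
    idx <- pmin(pmax(round(centers), xs[1L]), xs[n]) - xs[1L] + 1L
    m <- matrix(0, length(centers), n)
    m[cbind(seq_along(centers), idx)] <- 1
    return(m)
  }
  # CDF at all cell edges, per center
  ph <- stats::pnorm(outer(-centers, edges, "+") / sigma0)
  mass <- ph[, -1L, drop = FALSE] - ph[, -(n + 1L), drop = FALSE]
  tot <- ph[, n + 1L] - ph[, 1L]
  # Degenerate centers far outside the range: fall back to nearest bound.
  bad <- tot <= 0
  out <- mass / pmax(tot, .Machine$double.xmin)
  if (any(bad)) {
    out[bad, ] <- 0
    idx <- ifelse(centers[bad] < xs[1L], 1L, n)
    out[cbind(which(bad), idx)] <- 1
  }
  out
}

#' Response distribution of the estimation observer
#'
#' Probability mass function of the recorded integer estimate given a
#' presented number: the Gaussian representation is integrated out by
#' fixed quadrature, the Bayesian posterior mean is computed at each
#' node, and the motor stage (truncated normal of sd `sigma0`, rounded to
#' the nearest in-range integer) maps each decoded value to response
#' cells.
#'
#' @param x presented number, inside the prior range.
#' @param enc an [encoding_spec()].
#' @param sigma0 motor-noise standard deviation, `>= 0` (0 gives a
#'   point-mass motor stage at the rounded posterior mean).
#' @param prior a [prior_spec()].
#' @param n_nodes number of quadrature nodes over the representation,
#'   spanning `mu(x) +/- 6 nu w^alpha`.
#' @return a list with `support` (integers of the range) and `mass`
#'   (probabilities summing to 1).
#' @examples
#' p <- prior_spec(50, 70)
#' pmf <- response_pmf(60, encoding_spec("linear", 1, 0.5), 3, p)
#' sum(pmf$mass)
#' @export
response_pmf <- function(x, enc, sigma0, prior, n_nodes = 201) {
  stopifnot(inherits(enc, "encoding_spec"), inherits(prior, "prior_spec"))
  stopifnot_scalar(sigma0, "sigma0")
  if (sigma0 < 0) stop("'sigma0' must be >= 0", call. = FALSE)
  if (x < prior$x_min || x > prior$x_max)
    stop("'x' must lie inside the prior range", call. = FALSE)
  s <- encoding_sd(enc, prior$width)
  if (s <= 0) {
    # No cognitive noise: the representation is exact and the decoded
    # value is the presented number itself.
    mass <- motor_kernel(x, sigma0, prior)[1L, ]
    return(list(support = prior$support, mass = as.numeric(mass)))
  }
  g <- trapz_grid(mu(x, enc$kind) - 6 * s, mu(x, enc$kind) + 6 * s, n_nodes)
  wq <- g$w * stats::dnorm(g$x, mu(x, enc$kind), s)
  wq <- wq / sum(wq)
  xstar <- posterior_mean(g$x, enc, prior)
  mass <- as.numeric(wq %*% motor_kernel(xstar, sigma0, prior))
  list(support = prior$support, mass = mass / sum(mass))
}

# Fast shared-grid version: the full matrix P(xhat | x) for every x in
# the prior support, computed on a single representation grid covering
# all stimuli.  Mathematically the same integral as response_pmf; used by
# the likelihood code where the per-stimulus quadrature would recompute
# the decoded values many times over.
response_pmf_matrix <- function(enc, sigma0, prior) {
  s <- encoding_sd(enc, prior$width)
  xs <- prior$support
  if (s <= 0) {
    m <- motor_kernel(xs, sigma0, prior)
    dimnames(m) <- list(xs, xs)
    return(m)
  }
  mus <- mu(xs, enc$kind)
  # Grid resolution: fine relative to both the representation sd and the
  # narrowest rounding cell mapped into representation space.
  cell <- min(mu_prime(xs, enc$kind)) * max(sigma0, 0.5)
  h <- min(s / 6, cell / 4)
  lo <- min(mus) - 6 * s
  hi <- max(mus) + 6 * s
  n <- min(8001L, max(401L, ceiling((hi - lo) / h) + 1L))
  g <- trapz_grid(lo, hi, n)
  xstar <- posterior_mean(g$x, enc, prior)
  M <- motor_kernel(xstar, sigma0, prior)           # n x n_support
  W <- outer(mus, g$x, function(m, r) stats::dnorm(r, m, s))
  W <- W * rep(g$w, each = length(xs))
  W <- W / rowSums(W)
  P <- W %*% M                                       # n_x x n_response
  dimnames(P) <- list(xs, xs)
  P / rowSums(P)
}

#' Choice probability in the discrimination (and risky-choice) task
#'
#' The two stream averages are encoded independently with the same noise
#' `nu * w^alpha`; the observer chooses the stream whose decoded value is
#' larger, which happens exactly when its representation is larger. With
#' a lapse probability `eta` (either response with probability 1/2) and
#' an optional bias against the second option,
#' `P(red) = (1 - eta) * Phi((mu(x_R) - mu(x_B) - bias) / (sqrt(2) nu w^alpha)) + eta / 2`.
#'
#' @param x_B,x_R the two option values ("blue" and "red" averages; for
#'   risky choice, the certain amount and the lottery's expected value).
#' @param enc an [encoding_spec()] with `nu > 0`.
#' @param w prior width of the condition.
#' @param eta lapse probability in `[0, 1]`.
#' @param bias additive bias subtracted from the evidence for "red"
#'   before scaling (0 for the symmetric discrimination task).
#' @return probability of choosing "red", vectorized over `x_B`, `x_R`.
#' @examples
#' choice_probability(50, 55, encoding_spec("linear", 0.22, 0.75), w = 30)
#' @export
choice_probability <- function(x_B, x_R, enc, w, eta = 0, bias = 0) {
  stopifnot(inherits(enc, "encoding_spec"))
  stopifnot_scalar(w, "w", positive = TRUE)
  stopifnot_scalar(eta, "eta")
  stopifnot_scalar(bias, "bias")
  if (eta < 0 || eta > 1) stop("'eta' must be in [0, 1]", call. = FALSE)
  s <- encoding_sd(enc, w)
  if (s <= 0) stop("choice_probability requires nu > 0", call. = FALSE)
  z <- (mu(x_R, enc$kind) - mu(x_B, enc$kind) - bias) / (sqrt(2) * s)
  (1 - eta) * stats::pnorm(z) + eta / 2
}

#' Range-normalization baseline response
#'
#' The non-Bayesian baseline: the number is mapped onto the unit range,
#' `(x - x_min)/w`, read with additive noise of sd `nu_tilde`, rescaled
#' back (`xhat = x_min + r w`), and passed through the same truncated,
#' rounded motor stage as the Bayesian observer. Before truncation the
#' response variance is `sigma0^2 + nu_tilde^2 w^2`: an affine function
#' of the squared prior width, the signature this baseline is tested
#' against.
#'
#' @param x presented number(s), inside the prior range.
#' @param prior a [prior_spec()].
#' @param nu_tilde readout noise sd on the unit scale.
#' @param sigma0 motor noise sd.
#' @return integer estimates, one per element of `x`, drawn with the
#'   session RNG.
#' @examples
#' set.seed(1)
#' range_normalized_response(rep(60, 5), prior_spec(50, 70), 0.1, 0)
#' @export
range_normalized_response <- function(x, prior, nu_tilde, sigma0) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(x < prior$x_min | x > prior$x_max))
    stop("'x' must lie inside the prior range", call. = FALSE)
  r <- (x - prior$x_min) / prior$width +
    stats::rnorm(length(x), 0, nu_tilde)
  center <- prior$x_min + r * prior$width
  sample_motor(center, sigma0, prior)
}

# Draw one integer response per center from the truncated, rounded motor
# stage (vectorized inverse-CDF draw).
sample_motor <- function(centers, sigma0, prior) {
  if (sigma0 <= 0) {
    return(as.integer(pmin(pmax(round(centers), prior$x_min), prior$x_max)))
  }
  lo <- stats::pnorm(prior$x_min, centers, sigma0)
  hi <- stats::pnorm(prior$x_max, centers, sigma0)
  u <- stats::runif(length(centers), lo, hi)
  draw <- stats::qnorm(pmin(pmax(u, 1e-300), 1 - 1e-16), centers, sigma0)
  as.integer(pmin(pmax(round(draw), prior$x_min), prior$x_max))
}
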