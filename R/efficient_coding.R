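# Resource-rational allocation of encoding precision.
#
# The observer accumulates n i.i.d. signals; a single signal's Fisher
# information I1(x) obeys the budget  integral sqrt(I1) dx <= sqrt(K),
# and each signal costs lambda.  The observer minimizes
#   L_a[n I1] + lambda n,   L_a[I] = integral pi(x)^a / I(x) dx,
# with a = 1 for an estimation (squared-error) objective and a = 2 for a
# discrimination objective.  The closed-form solution makes the total
# Fisher information pi^{2a/3} / sqrt(theta * integral pi^{a/3}), with
# theta = lambda / K, so on a uniform prior of width w the imprecision
# 1/sqrt(I) scales as w^{1/2} (a = 1) and w^{3/4} (a = 2).

#' Continuous-prior allocation problem
#'
#' @param xs grid over the support (strictly increasing).
#' @param pi_x prior density on the grid; it is renormalized to
#'   integrate to 1 by the trapezoid rule.
#' @param a task exponent: 1 for estimation, 2 for discrimination
#'   (other positive values accepted for testing).
#' @param lam per-signal cost `lambda > 0`.
#' @param K single-signal Fisher budget `K > 0`.
#' @return an object of class `allocation_problem` with `theta = lam/K`.
#' @examples
#' g <- seq(0, 1, length.out = 256)
#' allocation_problem(g, rep(1, 256), a = 1)
#' @export
allocation_problem <- function(xs, pi_x, a, lam = 1, K = 1) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(lam, "lam", positive = TRUE)
  stopifnot_scalar(K, "K", positive = TRUE)
  if (length(xs) != length(pi_x) || any(diff(xs) <= 0))
    stop("'xs' must be strictly increasing and match 'pi_x'", call. = FALSE)
  if (any(pi_x < 0)) stop("'pi_x' must be nonnegative", call. = FALSE)
  z <- trapz(xs, pi_x)
  if (z <= 0) stop("'pi_x' integrates to zero", call. = FALSE)
  structure(list(xs = xs, pi_x = pi_x / z, a = a, lam = lam, K = K,
                 theta = lam / K),
            class = "allocation_problem")
}

#' Fisher-information profile
#'
#' A gridded Fisher-information function together with the (continuous)
#' signal count `n`; total information is `n * I1` when built from a
#' single-signal profile.
#'
#' @param xs grid.
#' @param I Fisher-information values, `>= 0`.
#' @param n signal count, `>= 0`.
#' @return an object of class `fisher_profile`.
#' @export
fisher_profile <- function(xs, I, n = 1) {
  if (any(I < 0)) stop("Fisher information must be >= 0", call. = FALSE)
  structure(list(xs = xs, I = I, n = n), class = "fisher_profile")
}

#' Task loss of a Fisher profile
#'
#' `L_a[I] = integral pi(x)^a / I(x) dx`, evaluated by the trapezoid
#' rule. Grid points where the prior vanishes contribute nothing; if the
#' information vanishes where the prior does not, the loss is infinite.
#'
#' @param profile a [fisher_profile()] holding the *total* information.
#' @param prob an [allocation_problem()] (its grid must match).
#' @return the numerical loss (possibly `Inf`).
#' @examples
#' g <- seq(0, 2, length.out = 128)
#' pr <- allocation_problem(g, rep(0.5, 128), a = 1)
#' loss(fisher_profile(g, rep(4, 128)), pr)  # 1/4
#' @export
loss <- function(profile, prob) {
  stopifnot(inherits(profile, "fisher_profile"),
            inherits(prob, "allocation_problem"))
  if (!isTRUE(all.equal(profile$xs, prob$xs)))
    stop("profile and problem grids differ", call. = FALSE)
  num <- prob$pi_x^prob$a
  bad <- num > 0 & profile$I <= 0
  if (any(bad)) return(Inf)
  integrand <- ifelse(num > 0, num / profile$I, 0)
  trapz(prob$xs, integrand)
}

#' Budget functional of a single-signal profile
#'
#' `integral sqrt(I1(x)) dx`; at the optimum it saturates `sqrt(K)`.
#'
#' @param profile a [fisher_profile()] holding `I1`.
#' @return the numerical value of the constraint integral.
#' @export
constraint_value <- function(profile) {
  stopifnot(inherits(profile, "fisher_profile"))
  trapz(profile$xs, sqrt(profile$I))
}

#' Optimal single-signal information on a uniform prior
#'
#' With the signal count fixed at one, the budget-saturating optimum on
#' a uniform prior of width `w` is flat: `I1 = K / w^2` on the support
#' (independently of the task exponent). Its imprecision is proportional
#' to `w` — the scaling that the endogenous-`n` solution replaces.
#'
#' @param prior a uniform [prior_spec()].
#' @param K Fisher budget.
#' @param grid_size grid points over the support.
#' @return a [fisher_profile()] with `n = 1`.
#' @examples
#' single_signal_optimum(prior_spec(0, 10), K = 100)$I[1]  # 1
#' @export
single_signal_optimum <- function(prior, K = 1, grid_size = 512) {
  if (!inherits(prior, "prior_spec"))
    stop("'prior' must be a uniform prior_spec; for non-uniform priors ",
         "use brute_force_allocation", call. = FALSE)
  xs <- seq(prior$x_min, prior$x_max, length.out = grid_size)
  fisher_profile(xs, rep(K / prior$width^2, grid_size), n = 1)
}

#' Optimal signal count
#'
#' Treating the signal count as continuous, the optimum on a uniform
#' prior of width `w` is `n = w^((3 - a)/2) / sqrt(lambda K)`:
#' proportional to `w` for the estimation objective and to `sqrt(w)` for
#' the discrimination objective.
#'
#' @param w prior width.
#' @param a task exponent.
#' @param lam,K cost and budget.
#' @return the optimal continuous signal count.
#' @examples
#' optimal_n(9, a = 1)  # 9
#' optimal_n(9, a = 2)  # 3
#' @export
optimal_n <- function(w, a, lam = 1, K = 1) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(lam, "lam", positive = TRUE)
  stopifnot_scalar(K, "K", positive = TRUE)
  w^((3 - a) / 2) / sqrt(lam * K)
}

#' Optimal total Fisher information (general prior)
#'
#' The joint optimum over the signal profile and the signal count:
#' `I(x) = pi(x)^(2a/3) / sqrt(theta * integral pi^(a/3))`, zero outside
#' the support of the prior.
#'
#' @param prob an [allocation_problem()].
#' @return a [fisher_profile()] holding the total information, with `n`
#'   set to the optimal signal count.
#' @examples
#' g <- seq(0, 4, length.out = 256)
#' p <- allocation_problem(g, rep(0.25, 256), a = 1)
#' optimal_total_fisher(p)$I[1]  # 0.25
#' @export
optimal_total_fisher <- function(prob) {
  stopifnot(inherits(prob, "allocation_problem"))
  z <- trapz(prob$xs, prob$pi_x^(prob$a / 3))
  I <- prob$pi_x^(2 * prob$a / 3) / sqrt(prob$theta * z)
  n <- z^(3 / 2) / sqrt(prob$lam * prob$K)
  fisher_profile(prob$xs, I, n = n)
}

#' Optimal total Fisher information (uniform prior, closed form)
#'
#' On a uniform prior of width `w` the optimal total information is
#' constant: `1/(sqrt(theta) w)` for the estimation objective (`a = 1`)
#' and `1/(sqrt(theta) w^(3/2))` for the discrimination objective
#' (`a = 2`).
#'
#' @param w prior width.
#' @param a task exponent, 1 or 2 (other values: use
#'   [optimal_total_fisher()]).
#' @param theta cost-to-budget ratio `lambda / K`.
#' @return the constant information level.
#' @examples
#' uniform_total_fisher(100, a = 1)  # 0.01
#' @export
uniform_total_fisher <- function(w, a, theta = 1) {
  stopifnot_scalar(theta, "theta", positive = TRUE)
  if (!a %in% c(1, 2))
    stop("closed form covers a = 1 or 2; use optimal_total_fisher",
         call. = FALSE)
  if (a == 1) 1 / (sqrt(theta) * w) else 1 / (sqrt(theta) * w^(3 / 2))
}

#' Predicted width-scaling exponent of the imprecision
#'
#' Least-squares slope of `log(1/sqrt(I))` against `log w` across
#' uniform priors of the given widths — the exponent `alpha` that the
#' behavioral model should exhibit. With the closed form the slope is
#' exact (`(1 + a)/4`, i.e. 1/2 or 3/4); with `oracle = TRUE` the
#' information levels are obtained from the numerical optimizer instead.
#'
#' @param widths two or more distinct prior widths.
#' @param a task exponent.
#' @param theta cost-to-budget ratio.
#' @param oracle if `TRUE`, solve each width's allocation numerically
#'   with [brute_force_allocation()] and use the midpoint information.
#' @param grid_size oracle grid resolution.
#' @return the fitted exponent.
#' @examples
#' scaling_exponent(c(20, 40, 60), a = 1)  # 0.5
#' scaling_exponent(c(30, 80), a = 2)      # 0.75
#' @export
scaling_exponent <- function(widths, a, theta = 1, oracle = FALSE,
                             grid_size = 512) {
  if (length(unique(widths)) < 2)
    stop("need at least two distinct widths", call. = FALSE)
  I <- vapply(widths, function(w) {
    if (!oracle) return(uniform_total_fisher(w, a, theta))
    xs <- seq(0, w, length.out = grid_size)
    prob <- allocation_problem(xs, rep(1 / w, grid_size), a = a,
                               lam = theta, K = 1)
    prof <- brute_force_allocation(prob)
    mid <- which.min(abs(xs - w / 2))
    prof$n * prof$I[mid]
  }, numeric(1))
  imprecision <- 1 / sqrt(I)
  as.numeric(stats::coef(stats::lm(log(imprecision) ~ log(widths)))[2])
}

#' Log-constrained single-signal information
#'
#' When the signal's information is constrained to the `1/x^2` shape of
#' a logarithmic transducer, the budget pins down the level:
#' `I1(x) = K / (x^2 log^2(x1/x0))` on `[x0, x1]`.
#'
#' @param x0,x1 prior bounds, `0 < x0 < x1`.
#' @param K Fisher budget.
#' @param grid_size grid points.
#' @return a [fisher_profile()] with `n = 1`.
#' @examples
#' pf <- log_constrained_single_signal(1, exp(1), K = 1)
#' constraint_value(pf)  # 1
#' @export
log_constrained_single_signal <- function(x0, x1, K = 1, grid_size = 512) {
  stopifnot_scalar(x0, "x0")
  stopifnot_scalar(x1, "x1")
  if (x0 <= 0 || x1 <= x0)
    stop("need 0 < x0 < x1", call. = FALSE)
  xs <- seq(x0, x1, length.out = grid_size)
  fisher_profile(xs, K / (xs^2 * log(x1 / x0)^2), n = 1)
}

#' Log-constrained total Fisher information
#'
#' Joint optimum of the allocation problem when the single-signal shape
#' is constrained to `1/x^2`, on a uniform prior centered at `x_mid`
#' with half-width `h`. The exact solution is
#' `I(x) = sqrt(K / (3 lambda 2^a)) * sqrt((x1^3 - x0^3)/h^a) / (log(x1/x0) x^2)`
#' and its leading-order expansion in `h/x_mid` is
#' `sqrt(K/lambda) (2h)^(-(1+a)/2) (x_mid/x)^2`, with a relative deficit
#' of `(1/6)(h/x_mid)^2` at second order. Both are returned along with
#' the ratio, so the small-width limit can be inspected directly.
#'
#' @param x_mid prior midpoint.
#' @param h half-width, `0 < h < x_mid`.
#' @param a task exponent.
#' @param lam,K cost and budget.
#' @param grid_size grid points.
#' @return a list with the exact `profile` (a [fisher_profile()] of the
#'   total information), `leading` (the leading-order values on the same
#'   grid), `ratio` (exact/leading, constant across `x`), and
#'   `rel_deficit` (`1 - ratio`).
#' @examples
#' out <- log_constrained_total_fisher(60, 0.6, a = 1)
#' abs(out$ratio - 1) < 1e-3
#' @export
log_constrained_total_fisher <- function(x_mid, h, a, lam = 1, K = 1,
                                         grid_size = 512) {
  stopifnot_scalar(x_mid, "x_mid", positive = TRUE)
  stopifnot_scalar(h, "h", positive = TRUE)
  if (h >= x_mid) stop("need 0 < h < x_mid", call. = FALSE)
  x0 <- x_mid - h
  x1 <- x_mid + h
  xs <- seq(x0, x1, length.out = grid_size)
  exact <- sqrt(K / (3 * lam * 2^a)) *
    sqrt((x1^3 - x0^3) / h^a) / (log(x1 / x0) * xs^2)
  leading <- sqrt(K / lam) * (2 * h)^(-(1 + a) / 2) * (x_mid / xs)^2
  ratio <- exact[1] / leading[1]   # x-independent: both fall as 1/x^2
  list(profile = fisher_profile(xs, exact, n = NA_real_),
       leading = leading, ratio = ratio, rel_deficit = 1 - ratio)
}

#' Numerical solution of the allocation problem
#'
#' Independent oracle for the closed forms: minimizes
#' `L_a[n I1] + lambda n` over a nonnegative gridded single-signal
#' profile and a continuous signal count. The profile is parameterized
#' through `s(x) = sqrt(I1(x))`, in which the budget is linear and, at
#' the optimum, active; the scale of `s` is fixed by the saturated
#' budget and the signal count is profiled out in closed form
#' (`n* = sqrt(L / lambda)` for loss `L` at `n = 1`), leaving a smooth
#' unconstrained problem solved by BFGS with an analytic gradient from a
#' flat start.
#'
#' @param prob an [allocation_problem()].
#' @param grid_size if given, the problem is re-gridded to this many
#'   points (minimum 32).
#' @param maxit BFGS iteration cap.
#' @return a [fisher_profile()] holding the optimal `I1` with the
#'   optimal `n`; attributes `objective` (achieved value of the full
#'   objective) and `convergence` (optim code).
#' @examples
#' g <- seq(0, 2, length.out = 64)
#' p <- allocation_problem(g, rep(0.5, 64), a = 1)
#' prof <- brute_force_allocation(p)
#' @export
brute_force_allocation <- function(prob, grid_size = NULL, maxit = 500) {
  stopifnot(inherits(prob, "allocation_problem"))
  if (!is.null(grid_size)) {
    if (grid_size < 32) stop("'grid_size' must be >= 32", call. = FALSE)
    xs <- seq(min(prob$xs), max(prob$xs), length.out = grid_size)
    pi_x <- stats::approx(prob$xs, prob$pi_x, xs)$y
    prob <- allocation_problem(xs, pi_x, prob$a, prob$lam, prob$K)
  }
  xs <- prob$xs
  m <- length(xs)
  h <- diff(xs)
  wq <- c(h / 2, 0) + c(0, h / 2)            # trapezoid weights
  c_i <- wq * prob$pi_x^prob$a               # loss coefficients
  sqK <- sqrt(prob$K)

  # C(u) = sum c_i / s_i^2 with s = sqK * exp(u) / (sum wq exp(u));
  # the full objective is 2 * sqrt(lam * C) after profiling out n.
  cfun <- function(u) {
    e <- exp(u - max(u))
    tot <- sum(wq * e)
    s <- sqK * e / tot
    sum(c_i / s^2)
  }
  gfun <- function(u) {
    e <- exp(u - max(u))
    tot <- sum(wq * e)
    s <- sqK * e / tot
    term <- c_i / s^2
    C <- sum(term)
    -2 * term + 2 * (wq * e / tot) * C
  }
  fit <- stats::optim(rep(0, m), fn = function(u) log(cfun(u)),
                      gr = function(u) gfun(u) / cfun(u),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  if (fit$convergence != 0 && fit$convergence != 1)
    stop(sprintf("allocation optimizer failed (code %d): %s",
                 fit$convergence, fit$message), call. = FALSE)
  u <- fit$par
  e <- exp(u - max(u))
  s <- sqK * e / sum(wq * e)
  I1 <- s^2
  C <- sum(c_i / I1)
  n <- sqrt(C / prob$lam)
  prof <- fisher_profile(xs, I1, n = n)
  attr(prof, "objective") <- 2 * sqrt(prob$lam * C)
  attr(prof, "convergence") <- fit$convergence
  prof
}
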