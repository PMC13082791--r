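# Maximum-likelihood fitting of the observer models and the model
# comparison machinery (BIC grids, magnitude-split probit, KS
# distribution matching, random-effects Bayesian model selection).

#' Bayesian Information Criterion
#'
#' @param logL maximized log-likelihood.
#' @param k number of free parameters.
#' @param N number of observations.
#' @return `k * log(N) - 2 * logL` (lower is better).
#' @examples
#' bic(-5, 2, 10)
#' @export
bic <- function(logL, k, N) {
  if (N < 1 || k < 0) stop("need N >= 1 and k >= 0", call. = FALSE)
  k * log(N) - 2 * logL
}

new_fit_result <- function(structure, params, logL, k, N) {
  structure(list(structure = structure, params = params, logL = logL,
                 k = k, N = N, bic = bic(logL, k, N)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit [%s]: logL = %.2f, k = %d, N = %d, BIC = %.2f\n",
              x$structure, x$logL, x$k, x$N, x$bic))
  pp <- unlist(x$params)
  cat(paste(sprintf("  %s = %.4g", names(pp), pp), collapse = "\n"), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------
# Estimation task
# ---------------------------------------------------------------------

# Resolve the priors attached to a table (or fall back to the standard
# conditions present in it).
table_priors <- function(table, priors = NULL, task = "estimation") {
  if (!is.null(priors)) return(priors)
  pr <- attr(table, "priors")
  if (!is.null(pr)) return(pr)
  std <- if (task == "estimation") estimation_priors() else
    discrimination_priors()
  std[intersect(names(std), unique(table$condition))]
}

#' Negative log-likelihood of estimation responses
#'
#' Sums `-log P(response | x)` under the observer's exact response
#' distribution, with the imprecision and motor-noise parameters either
#' shared or given per subject. Responses outside their condition's
#' prior range are a data error, not silently dropped.
#'
#' @param table an estimation trial table (`subject`, `condition`, `x`,
#'   `response`).
#' @param nu baseline imprecision: a scalar, or a vector indexed by
#'   subject id.
#' @param sigma0 motor noise sd: scalar or vector indexed by subject id.
#' @param alpha width-scaling exponent (shared).
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param priors named list of [prior_spec()] per condition; defaults to
#'   the table's attached priors.
#' @return the negative log-likelihood.
#' @export
estimation_nll <- function(table, nu, sigma0, alpha,
                           encoding = "linear", priors = NULL) {
  priors <- table_priors(table, priors)
  for (cn in unique(table$condition)) {
    p <- priors[[cn]]
    rows <- table$condition == cn
    if (any(table$x[rows] < p$x_min | table$x[rows] > p$x_max |
            table$response[rows] < p$x_min | table$response[rows] > p$x_max))
      stop(sprintf("condition '%s': x or response outside prior range", cn),
           call. = FALSE)
  }
  subj_ids <- sort(unique(table$subject))
  nu_of <- function(s) if (length(nu) == 1L) nu else nu[[as.character(s)]]
  s0_of <- function(s) if (length(sigma0) == 1L) sigma0 else
    sigma0[[as.character(s)]]
  nll <- 0
  for (cn in unique(table$condition)) {
    p <- priors[[cn]]
    sub <- table[table$condition == cn, , drop = FALSE]
    if (length(nu) == 1L && length(sigma0) == 1L) {
      groups <- list(sub)
      pars <- list(c(nu, sigma0))
    } else {
      groups <- split(sub, sub$subject)
      pars <- lapply(names(groups),
                     function(s) c(nu_of(s), s0_of(s)))
    }
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      enc <- encoding_spec(encoding, pars[[gi]][1], alpha)
      P <- response_pmf_matrix(enc, pars[[gi]][2], p)
      ix <- g$x - p$x_min + 1L
      ir <- g$response - p$x_min + 1L
      pv <- P[cbind(ix, ir)]
      nll <- nll - sum(log(pmax(pv, 1e-300)))
    }
  }
  nll
}

# Deterministic multi-start grid for the estimation fits.
estimation_starts <- function() {
  g <- expand.grid(nu = c(0.5, 1.5), sigma0 = c(2, 6),
                   alpha = c(0.3, 0.9))
  rbind(g, data.frame(nu = c(1, 0.8), sigma0 = c(3, 4),
                      alpha = c(0.5, 1.2)))
}

# Bounded fit of (nu, sigma0, alpha) on one table chunk with shared
# parameters; alpha may be fixed.
fit_est_shared <- function(table, alpha_fixed, encoding, priors, starts) {
  counts <- stats::aggregate(
    list(n = rep(1L, nrow(table))),
    by = list(condition = table$condition, x = table$x,
              response = table$response), FUN = sum)
  nll_counts <- function(nu, sigma0, alpha) {
    nll <- 0
    for (cn in unique(counts$condition)) {
      p <- priors[[cn]]
      cc <- counts[counts$condition == cn, ]
      enc <- encoding_spec(encoding, nu, alpha)
      P <- response_pmf_matrix(enc, sigma0, p)
      pv <- P[cbind(cc$x - p$x_min + 1L, cc$response - p$x_min + 1L)]
      nll <- nll - sum(cc$n * log(pmax(pv, 1e-300)))
    }
    nll
  }
  free_alpha <- is.null(alpha_fixed)
  obj <- function(par) {
    a <- if (free_alpha) par[3] else alpha_fixed
    nll_counts(exp(par[1]), exp(par[2]), a)
  }
  lower <- c(log(1e-4), log(1e-3), if (free_alpha) 0)
  upper <- c(log(50), log(50), if (free_alpha) 1.5)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$nu[i]), log(starts$sigma0[i]),
            if (free_alpha) starts$alpha[i])
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 300, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  list(nu = exp(best$par[1]), sigma0 = exp(best$par[2]),
       alpha = if (free_alpha) best$par[3] else alpha_fixed,
       nll = best$value)
}

# sigma0-only fit (no cognitive noise) on one chunk.
fit_est_motor_only <- function(table, priors) {
  obj <- function(ls0) {
    nll <- 0
    for (cn in unique(table$condition)) {
      p <- priors[[cn]]
      sub <- table[table$condition == cn, ]
      P <- motor_kernel(sub$x, exp(ls0), p)
      pv <- P[cbind(seq_len(nrow(sub)), sub$response - p$x_min + 1L)]
      nll <- nll - sum(log(pmax(pv, 1e-300)))
    }
    nll
  }
  fit <- stats::optimize(obj, c(log(0.1), log(50)))
  list(sigma0 = exp(fit$minimum), nll = fit$objective)
}

#' Fit the estimation observer model
#'
#' Maximum-likelihood fit under the model structures of the estimation
#' task's comparison grid: the exponent fixed or free; the imprecision
#' and motor-noise parameters shared across subjects or individual; and
#' a no-cognitive-noise variant. Individual-parameter structures are fit
#' subject by subject (they are independent given the shared exponent);
#' a free shared exponent over individual parameters is profiled by an
#' outer univariate search on `[0, 1.5]`.
#'
#' @param table an estimation trial table.
#' @param alpha `"free"` or a fixed numeric value.
#' @param nu_mode `"shared"`, `"individual"`, or `"zero"` (motor noise
#'   only; `alpha` is then meaningless and ignored).
#' @param sigma0_mode `"shared"` or `"individual"`.
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param priors optional condition priors (defaults to the table's).
#' @param starts data frame of start points for the shared-parameter
#'   searches (default a fixed 10-point grid).
#' @return a `fit_result` with fields `structure`, `params`, `logL`,
#'   `k`, `N`, `bic`.
#' @export
fit_estimation <- function(table, alpha = "free",
                           nu_mode = c("shared", "individual", "zero"),
                           sigma0_mode = c("shared", "individual"),
                           encoding = "linear", priors = NULL,
                           starts = estimation_starts()) {
  nu_mode <- match.arg(nu_mode)
  sigma0_mode <- match.arg(sigma0_mode)
  priors <- table_priors(table, priors)
  N <- nrow(table)
  subj_ids <- sort(unique(table$subject))
  ns <- length(subj_ids)
  alpha_fixed <- if (identical(alpha, "free")) NULL else as.numeric(alpha)

  if (nu_mode == "zero") {
    if (sigma0_mode == "shared") {
      f <- fit_est_motor_only(table, priors)
      return(new_fit_result("nu=0 | sigma0 shared",
                            list(sigma0 = f$sigma0), -f$nll, 1L, N))
    }
    fits <- lapply(subj_ids, function(s)
      fit_est_motor_only(table[table$subject == s, ], priors))
    nll <- sum(vapply(fits, `[[`, numeric(1), "nll"))
    s0 <- vapply(fits, `[[`, numeric(1), "sigma0")
    names(s0) <- subj_ids
    return(new_fit_result("nu=0 | sigma0 individual",
                          list(sigma0 = s0), -nll, ns, N))
  }

  shared_all <- nu_mode == "shared" && sigma0_mode == "shared"
  if (shared_all) {
    f <- fit_est_shared(table, alpha_fixed, encoding, priors, starts)
    k <- 2L + is.null(alpha_fixed)
    lab <- sprintf("alpha %s | nu shared | sigma0 shared",
                   if (is.null(alpha_fixed)) "free" else
                     sprintf("= %.3g", alpha_fixed))
    return(new_fit_result(lab, f[c("nu", "sigma0", "alpha")],
                          -f$nll, k, N))
  }

  # Individual parameters: subjects decouple given alpha.
  fit_given_alpha <- function(a) {
    per <- lapply(subj_ids, function(s) {
      sub <- table[table$subject == s, , drop = FALSE]
      fit_est_shared(sub, a, encoding, priors, starts)
    })
    nll <- sum(vapply(per, `[[`, numeric(1), "nll"))
    list(nll = nll, per = per)
  }
  if (is.null(alpha_fixed)) {
    prof <- stats::optimize(function(a) fit_given_alpha(a)$nll,
                            c(0, 1.5), tol = 1e-3)
    a_hat <- prof$minimum
    res <- fit_given_alpha(a_hat)
    k_alpha <- 1L
  } else {
    a_hat <- alpha_fixed
    res <- fit_given_alpha(a_hat)
    k_alpha <- 0L
  }
  nu_hat <- vapply(res$per, `[[`, numeric(1), "nu")
  s0_hat <- vapply(res$per, `[[`, numeric(1), "sigma0")
  names(nu_hat) <- names(s0_hat) <- subj_ids
  # Individual structures here fit both nu and sigma0 per subject; the
  # parameter count reflects which are declared individual (a shared
  # parameter among per-subject fits is an approximation we do not
  # offer: modes are restricted accordingly).
  if (nu_mode != "individual" || sigma0_mode != "individual")
    stop("per-subject fitting supports nu_mode = sigma0_mode = ",
         "'individual' (or both 'shared')", call. = FALSE)
  k <- 2L * ns + k_alpha
  lab <- sprintf("alpha %s | nu individual | sigma0 individual",
                 if (is.null(alpha_fixed)) sprintf("free (%.3f)", a_hat)
                 else sprintf("= %.3g", alpha_fixed))
  new_fit_result(lab, list(nu = nu_hat, sigma0 = s0_hat, alpha = a_hat),
                 -res$nll, k, N)
}

#' BIC comparison grid for the estimation task
#'
#' Fits the shared-parameter model with the exponent fixed at 1, 1/2, 0
#' and free, plus the no-cognitive-noise variant, and tabulates BICs.
#'
#' @param table an estimation trial table.
#' @param encoding encoding used for all rows.
#' @param priors optional condition priors.
#' @return a `data.frame` ordered as fit, with a `fits` attribute
#'   holding the full `fit_result`s.
#' @export
estimation_bic_grid <- function(table, encoding = "linear", priors = NULL) {
  specs <- list(
    `alpha = 1`   = list(alpha = 1),
    `alpha = 1/2` = list(alpha = 0.5),
    `alpha free`  = list(alpha = "free"),
    `alpha = 0`   = list(alpha = 0),
    `nu = 0`      = list(alpha = 0, nu_mode = "zero")
  )
  fits <- lapply(specs, function(sp)
    fit_estimation(table, alpha = sp$alpha,
                   nu_mode = if (is.null(sp$nu_mode)) "shared" else
                     sp$nu_mode,
                   encoding = encoding, priors = priors))
  out <- data.frame(
    model = names(specs),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

# ---------------------------------------------------------------------
# Discrimination (and risky-choice) task
# ---------------------------------------------------------------------

#' Negative log-likelihood of discrimination choices
#'
#' Bernoulli likelihood of the observed choices under the observer's
#' choice probability, with shared `(nu, alpha, eta)` across conditions.
#'
#' @param table a discrimination trial table (`condition`, `x_R`, `x_B`,
#'   `choice`).
#' @param nu baseline imprecision.
#' @param alpha width-scaling exponent.
#' @param eta lapse probability.
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param bias additive bias (risky-choice variant; 0 otherwise).
#' @param priors optional condition priors.
#' @return the negative log-likelihood.
#' @export
discrimination_nll <- function(table, nu, alpha, eta = 0,
                               encoding = "linear", bias = 0,
                               priors = NULL) {
  if (!all(table$choice %in% c("red", "blue")))
    stop("choices must be 'red' or 'blue'", call. = FALSE)
  priors <- table_priors(table, priors, task = "discrimination")
  nll <- 0
  for (cn in unique(table$condition)) {
    sub <- table[table$condition == cn, ]
    w <- priors[[cn]]$width
    enc <- encoding_spec(encoding, nu, alpha)
    pr <- choice_probability(sub$x_B, sub$x_R, enc, w, eta = eta,
                             bias = bias)
    y <- sub$choice == "red"
    nll <- nll - sum(log(pmax(ifelse(y, pr, 1 - pr), 1e-300)))
  }
  nll
}

#' Fit the discrimination observer model (pooled conditions)
#'
#' Maximum-likelihood fit of `(nu, eta)` with the exponent fixed or
#' free. Separating `nu` from `alpha` requires at least two prior
#' widths; a single-condition table with a free exponent is an
#' identifiability error (fit `nu_tilde` per subject instead, see
#' [fit_discrimination_subjects()]).
#'
#' @param table a discrimination trial table.
#' @param alpha `"free"` or a fixed value.
#' @param lapse include a lapse probability?
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param bias `"free"`, or a fixed value (0 for the symmetric task).
#' @param priors optional condition priors.
#' @return a `fit_result`.
#' @export
fit_discrimination <- function(table, alpha = "free", lapse = TRUE,
                               encoding = "linear", bias = 0,
                               priors = NULL) {
  priors <- table_priors(table, priors, task = "discrimination")
  widths <- vapply(priors[unique(table$condition)], `[[`, numeric(1),
                   "width")
  free_alpha <- identical(alpha, "free")
  if (free_alpha && length(unique(widths)) < 2)
    stop("a free exponent is not identifiable from a single prior ",
         "width; fit nu_tilde instead", call. = FALSE)
  free_bias <- identical(bias, "free")
  alpha_fixed <- if (free_alpha) NULL else as.numeric(alpha)
  bias_fixed <- if (free_bias) NULL else as.numeric(bias)
  unpack <- function(par) {
    i <- 1L
    nu <- exp(par[i]); i <- i + 1L
    a <- if (free_alpha) { v <- par[i]; i <- i + 1L; v } else alpha_fixed
    e <- if (lapse) { v <- par[i]; i <- i + 1L; v } else 0
    b <- if (free_bias) par[i] else bias_fixed
    list(nu = nu, alpha = a, eta = e, bias = b)
  }
  obj <- function(par) {
    p <- unpack(par)
    discrimination_nll(table, p$nu, p$alpha, p$eta, encoding, p$bias,
                       priors)
  }
  lower <- c(log(1e-6), if (free_alpha) 0, if (lapse) 0,
             if (free_bias) -10)
  upper <- c(log(50), if (free_alpha) 1.5, if (lapse) 0.5,
             if (free_bias) 10)
  starts <- list(c(log(0.2), if (free_alpha) 0.5, if (lapse) 0.02,
                   if (free_bias) 0),
                 c(log(1), if (free_alpha) 1.0, if (lapse) 0.1,
                   if (free_bias) 0.3),
                 c(log(0.05), if (free_alpha) 0.75, if (lapse) 0.05,
                   if (free_bias) -0.3))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  p <- unpack(best$par)
  k <- 1L + free_alpha + lapse + free_bias
  lab <- sprintf("alpha %s | lapse %s%s",
                 if (free_alpha) sprintf("free (%.3f)", p$alpha) else
                   sprintf("= %.3g", p$alpha),
                 if (lapse) "yes" else "no",
                 if (free_bias) " | bias free" else "")
  new_fit_result(lab, p[c("nu", "alpha", "eta", "bias")], -best$value,
                 k, nrow(table))
}

#' Per-subject imprecision fits for single-condition data
#'
#' A subject who experienced a single prior width only identifies the
#' composite standard deviation `nu_tilde = nu * w^alpha`. This fits
#' `(nu_tilde, eta)` per subject by maximum likelihood.
#'
#' @param table a discrimination trial table.
#' @param lapse include a per-subject lapse probability?
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param priors optional condition priors.
#' @return a `data.frame` with one row per subject: `subject`,
#'   `condition`, `width`, `nu_tilde`, `eta`, `logL`.
#' @export
fit_discrimination_subjects <- function(table, lapse = TRUE,
                                        encoding = "linear",
                                        priors = NULL) {
  priors <- table_priors(table, priors, task = "discrimination")
  out <- lapply(split(table, table$subject), function(sub) {
    cn <- sub$condition[1L]
    w <- priors[[cn]]$width
    y <- sub$choice == "red"
    dmu <- mu(sub$x_R, encoding) - mu(sub$x_B, encoding)
    nllf <- function(nu_tilde, eta) {
      pr <- (1 - eta) * stats::pnorm(dmu / (sqrt(2) * nu_tilde)) + eta / 2
      -sum(log(pmax(ifelse(y, pr, 1 - pr), 1e-300)))
    }
    if (lapse) {
      fit <- stats::optim(c(log(1), 0.02),
                          function(p) nllf(exp(p[1]), p[2]),
                          method = "L-BFGS-B",
                          lower = c(log(1e-6), 0),
                          upper = c(log(1e3), 0.5))
      data.frame(subject = sub$subject[1L], condition = cn, width = w,
                 nu_tilde = exp(fit$par[1]), eta = fit$par[2],
                 logL = -fit$value)
    } else {
      fit <- stats::optimize(function(lv) nllf(exp(lv), 0),
                             c(log(1e-6), log(1e3)))
      data.frame(subject = sub$subject[1L], condition = cn, width = w,
                 nu_tilde = exp(fit$minimum), eta = 0,
                 logL = -fit$objective)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject), ]
}

#' BIC comparison grid for the discrimination task
#'
#' Fits the pooled model with the exponent fixed at 1, 3/4, 1/2 and
#' free, with and without lapses, and tabulates BICs.
#'
#' @inheritParams fit_discrimination
#' @return a `data.frame` with a `fits` attribute.
#' @export
discrimination_bic_grid <- function(table, encoding = "linear",
                                    priors = NULL) {
  specs <- expand.grid(alpha = c("1", "3/4", "1/2", "free"),
                       lapse = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(specs)), function(i) {
    a <- switch(specs$alpha[i], "1" = 1, "3/4" = 0.75, "1/2" = 0.5,
                "free" = "free")
    fit_discrimination(table, alpha = a, lapse = specs$lapse[i],
                       encoding = encoding, priors = priors)
  })
  out <- data.frame(
    alpha = specs$alpha, lapse = specs$lapse,
    k = vapply(fits, `[[`, numeric(1), "k"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  attr(out, "fits") <- fits
  out
}

# ---------------------------------------------------------------------
# Magnitude-split probit, KS matching, Bayesian model selection
# ---------------------------------------------------------------------

#' Magnitude-split lapse probit with likelihood-ratio test
#'
#' Restricts a condition's trials to those in which both averages fall
#' on the same side of a threshold, fits a lapse probit whose noise
#' scale may differ between the small-magnitude and large-magnitude
#' strata, and tests the equal-scale restriction by a likelihood-ratio
#' test against chi-squared(1).
#'
#' @param table a discrimination trial table (single condition).
#' @param threshold magnitude split point (default 50, the midpoint of
#'   the standard priors).
#' @return a list with `scale_small`, `scale_large`, `eta`, `LR_chi2`,
#'   `df`, `p`, and the stratum trial counts.
#' @export
split_magnitude_probit <- function(table, threshold = 50) {
  small <- table$x_R < threshold & table$x_B < threshold
  large <- table$x_R > threshold & table$x_B > threshold
  if (!any(small) || !any(large))
    stop("a magnitude stratum is empty", call. = FALSE)
  sub <- table[small | large, ]
  stratum <- ifelse(sub$x_R < threshold & sub$x_B < threshold,
                    "small", "large")
  y <- sub$choice == "red"
  d <- sub$x_R - sub$x_B
  nll2 <- function(ls1, ls2, eta) {
    sc <- ifelse(stratum == "small", exp(ls1), exp(ls2))
    pr <- (1 - eta) * stats::pnorm(d / sc) + eta / 2
    -sum(log(pmax(ifelse(y, pr, 1 - pr), 1e-300)))
  }
  f2 <- stats::optim(c(log(3), log(3), 0.02),
                     function(p) nll2(p[1], p[2], p[3]),
                     method = "L-BFGS-B",
                     lower = c(log(1e-3), log(1e-3), 0),
                     upper = c(log(1e3), log(1e3), 0.5))
  f1 <- stats::optim(c(log(3), 0.02),
                     function(p) nll2(p[1], p[1], p[2]),
                     method = "L-BFGS-B",
                     lower = c(log(1e-3), 0), upper = c(log(1e3), 0.5))
  LR <- max(0, 2 * (f1$value - f2$value))
  list(scale_small = exp(f2$par[1]), scale_large = exp(f2$par[2]),
       eta = f2$par[3], LR_chi2 = LR, df = 1L,
       p = stats::pchisq(LR, 1L, lower.tail = FALSE),
       n_small = sum(stratum == "small"),
       n_large = sum(stratum == "large"))
}

#' Distribution matching of rescaled imprecision across conditions
#'
#' Under the endogenous-precision account the per-subject composite
#' imprecision `nu_tilde = nu * w^alpha` should, once divided by
#' `w^alpha` with the correct exponent, have the same distribution in
#' every condition. Runs the two-sample Kolmogorov-Smirnov test on the
#' rescaled values.
#'
#' @param nu_tilde list of two numeric vectors (per-subject `nu_tilde`
#'   in each condition).
#' @param widths the two prior widths.
#' @param alpha rescaling exponent.
#' @return list with the KS statistic `D` and p-value `p`.
#' @export
ks_match <- function(nu_tilde, widths, alpha) {
  if (length(nu_tilde) != 2L || length(widths) != 2L)
    stop("need two samples and two widths", call. = FALSE)
  a <- nu_tilde[[1]] / widths[1]^alpha
  b <- nu_tilde[[2]] / widths[2]^alpha
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Random-effects Bayesian model selection
#'
#' Variational estimate of the population frequencies of competing
#' models from per-subject log model evidences (here approximated by
#' `-BIC/2`). Starting from a uniform Dirichlet, the posterior model
#' assignments and the Dirichlet concentration are iterated to
#' convergence; with two models the posterior over the frequency is a
#' Beta distribution.
#'
#' @param log_evidence a subjects x models matrix of log evidences.
#' @param alpha0 prior Dirichlet counts (default 1 per model).
#' @param tol convergence tolerance on the Dirichlet parameters.
#' @param max_iter iteration cap.
#' @return a list with `dirichlet` (posterior parameters),
#'   `expected_freq` (posterior mean frequencies), `concentration`
#'   (their sum) and `iterations`.
#' @export
bms_proportions <- function(log_evidence, alpha0 = NULL, tol = 1e-6,
                            max_iter = 10000) {
  log_evidence <- as.matrix(log_evidence)
  if (!all(is.finite(log_evidence)))
    stop("log evidences must be finite", call. = FALSE)
  K <- ncol(log_evidence)
  if (K < 2) stop("need at least two models", call. = FALSE)
  if (is.null(alpha0)) alpha0 <- rep(1, K)
  a <- alpha0
  for (it in seq_len(max_iter)) {
    lw <- sweep(log_evidence, 2L, digamma(a) - digamma(sum(a)), "+")
    lw <- lw - apply(lw, 1L, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    a_new <- alpha0 + colSums(u)
    if (max(abs(a_new - a)) < tol) {
      a <- a_new
      break
    }
    a <- a_new
  }
  list(dirichlet = a, expected_freq = a / sum(a),
       concentration = sum(a), iterations = it)
}
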