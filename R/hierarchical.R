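# Bayesian hierarchical mixed-effects model of estimation responses.
#
# Per condition c and presented number x there is a population mean
# m0[c,x] and population sd sigma0[c,x]; each subject s who saw that
# number has a subject mean m[s,c,x] shrunk toward m0 with sd tau, and
# a subject sd sigma[s,c,x] whose log is shrunk toward log sigma0 with
# sd nu_h.  Responses are Normal(m[s,c,x], sigma[s,c,x]^2).
# Hyperpriors: m0 ~ N(x, 20^2), sigma0 ~ N+(7, 7^2),
# tau ~ N+(5, 10^2), nu_h ~ N+(5, 10^2)  (N+ = normal truncated at 0).

# Index structures and sufficient statistics for the sampler and the
# log posterior.
hier_prepare <- function(table) {
  need <- c("subject", "condition", "x", "response")
  if (!all(need %in% names(table)))
    stop("table must have columns subject, condition, x, response",
         call. = FALSE)
  cell_key <- paste(table$condition, table$x, sep = ":")
  scell_key <- paste(table$subject, cell_key, sep = ":")
  cells <- sort(unique(cell_key))
  scells <- sort(unique(scell_key))
  j_of_row <- match(cell_key, cells)
  k_of_row <- match(scell_key, scells)
  # map subject-cell -> cell
  first_row <- match(scells, scell_key)
  j_of_k <- j_of_row[first_row]
  x_of_j <- table$x[match(cells, cell_key)]
  n_k <- tabulate(k_of_row, length(scells))
  sum_k <- as.numeric(tapply(table$response, k_of_row, sum))
  sumsq_k <- as.numeric(tapply(table$response^2, k_of_row, sum))
  list(cells = cells, scells = scells, j_of_k = j_of_k, x_of_j = x_of_j,
       n_k = n_k, sum_k = sum_k, sumsq_k = sumsq_k,
       n_rows = nrow(table))
}

# log density of the positive-truncated normal (with renormalization).
log_dnorm_pos <- function(x, mean, sd) {
  ifelse(x <= 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

#' Log posterior of the hierarchical estimation model
#'
#' Evaluates the joint log density of all parameters and the data:
#' response likelihood, subject-level shrinkage terms, and the
#' truncated-normal hyperpriors. Returns `-Inf` for out-of-domain
#' parameters (any nonpositive sd).
#'
#' @param params a list with `m0`, `sigma0` (vectors over condition x
#'   number cells, in the order of `prep$cells`), `m`, `sigma` (vectors
#'   over subject cells, order of `prep$scells`), `tau`, `nu`.
#' @param prep the output of `hier_prepare` — exposed via the `prep`
#'   element of [hier_sample()]'s return value, or built internally when
#'   a raw table is supplied.
#' @return the log posterior density (an unnormalized log joint).
#' @export
hier_log_posterior <- function(params, prep) {
  if (is.data.frame(prep)) prep <- hier_prepare(prep)
  with(params, {
    if (tau <= 0 || nu <= 0 || any(sigma0 <= 0) || any(sigma <= 0))
      return(-Inf)
    j <- prep$j_of_k
    sse <- prep$sumsq_k - 2 * m * prep$sum_k + prep$n_k * m^2
    ll <- sum(-prep$n_k * log(sigma) - sse / (2 * sigma^2)) -
      prep$n_rows * 0.5 * log(2 * pi)
    lp_m <- sum(stats::dnorm(m, m0[j], tau, log = TRUE))
    lp_s <- sum(stats::dnorm(log(sigma), log(sigma0[j]), nu, log = TRUE))
    lp_hyper <- sum(stats::dnorm(m0, prep$x_of_j, 20, log = TRUE)) +
      sum(log_dnorm_pos(sigma0, 7, 7)) +
      log_dnorm_pos(tau, 5, 10) + log_dnorm_pos(nu, 5, 10)
    ll + lp_m + lp_s + lp_hyper
  })
}

#' Simulate data from the hierarchical model
#'
#' Draws every parameter from its prior (so posterior intervals have
#' their nominal frequentist coverage over repeated simulations) and
#' generates Gaussian responses. Intended for calibration checks of the
#' sampler.
#'
#' @param n_subjects subjects per condition (all subjects see all
#'   numbers of their condition).
#' @param numbers named list: condition label -> vector of presented
#'   numbers (default: the full integer supports of the three standard
#'   estimation conditions).
#' @param trials_per_number repeated presentations of each number to
#'   each subject.
#' @param seed RNG seed.
#' @return a list with `table` (subject, condition, x, response) and
#'   `truth` (the generating parameter values, including per-cell
#'   `sigma0` keyed as `condition:x`).
#' @export
gen_hierarchical <- function(n_subjects = 12,
                             numbers = lapply(estimation_priors(),
                                              `[[`, "support"),
                             trials_per_number = 3, seed = 1) {
  set.seed(seed)
  rnorm_pos <- function(n, mean, sd) {
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(stats::runif(n, lo, 1), mean, sd)
  }
  tau <- rnorm_pos(1, 5, 10)
  nu <- rnorm_pos(1, 5, 10)
  rows <- list()
  truth_m0 <- c()
  truth_s0 <- c()
  for (cn in names(numbers)) {
    for (x in numbers[[cn]]) {
      m0 <- stats::rnorm(1, x, 20)
      s0 <- rnorm_pos(1, 7, 7)
      key <- paste(cn, x, sep = ":")
      truth_m0[key] <- m0
      truth_s0[key] <- s0
      for (s in seq_len(n_subjects)) {
        m_s <- stats::rnorm(1, m0, tau)
        sig_s <- exp(stats::rnorm(1, log(s0), nu))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste(cn, s, sep = "_"), condition = cn, x = x,
          response = stats::rnorm(trials_per_number, m_s, sig_s))
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table,
       truth = list(m0 = truth_m0, sigma0 = truth_s0, tau = tau,
                    nu = nu))
}

# One chain of the Metropolis-within-Gibbs sampler.  Means are updated
# by exact Gibbs draws (conjugate normals); log sds and the two hyper
# sds by univariate random-walk Metropolis with scales adapted during
# warmup.  Returns draws of m0, sigma0, tau, nu.
hier_chain <- function(prep, iter, warmup, seed) {
  set.seed(seed)
  J <- length(prep$cells)
  K <- length(prep$scells)
  j <- prep$j_of_k
  n_subj_j <- tabulate(j, J)
  ybar_k <- prep$sum_k / prep$n_k
  # init at data-driven values
  m <- ybar_k
  m0 <- as.numeric(tapply(m, j, mean))
  sse0 <- prep$sumsq_k - prep$n_k * ybar_k^2
  sig <- sqrt(pmax(sse0 / pmax(prep$n_k - 1, 1), 1))
  lsig <- log(sig)
  lsig0 <- as.numeric(tapply(lsig, j, mean))
  tau <- 5; nu <- 1
  step_s <- rep(0.5, K); step_s0 <- rep(0.3, J)
  step_t <- 0.3; step_n <- 0.3
  draws <- list(m0 = matrix(NA_real_, iter, J),
                sigma0 = matrix(NA_real_, iter, J),
                tau = numeric(iter), nu = numeric(iter))
  lp_sig <- function(ls) {
    s2 <- exp(2 * ls)
    sse <- prep$sumsq_k - 2 * m * prep$sum_k + prep$n_k * m^2
    -prep$n_k * ls - sse / (2 * s2) -
      (ls - lsig0[j])^2 / (2 * nu^2)
  }
  for (t in seq_len(warmup + iter)) {
    # Gibbs: subject means
    prec <- prep$n_k / exp(2 * lsig) + 1 / tau^2
    mean_m <- (prep$sum_k / exp(2 * lsig) + m0[j] / tau^2) / prec
    m <- stats::rnorm(K, mean_m, 1 / sqrt(prec))
    # Gibbs: population means (prior N(x, 20^2))
    sum_m_j <- as.numeric(rowsum(m, j))
    prec0 <- n_subj_j / tau^2 + 1 / 400
    mean0 <- (sum_m_j / tau^2 + prep$x_of_j / 400) / prec0
    m0 <- stats::rnorm(J, mean0, 1 / sqrt(prec0))
    # MH: subject log-sds (vectorized, independent conditionals)
    cur <- lp_sig(lsig)
    prop <- lsig + stats::rnorm(K, 0, step_s)
    new <- lp_sig(prop)
    # log-sd domain truncated to +/- 60 (guards against the funnel at
    # large nu driving sds to numerical under/overflow)
    new[abs(prop) > 60] <- -Inf
    acc <- log(stats::runif(K)) < new - cur
    lsig[acc] <- prop[acc]
    # MH: population log-sds
    sum_ls_j <- as.numeric(rowsum(lsig, j))
    sumsq_ls_j <- as.numeric(rowsum(lsig^2, j))
    lp_s0 <- function(l0) {
      s0 <- exp(l0)
      -(sumsq_ls_j - 2 * l0 * sum_ls_j + n_subj_j * l0^2) / (2 * nu^2) +
        log_dnorm_pos(s0, 7, 7) + l0
    }
    cur0 <- lp_s0(lsig0)
    prop0 <- lsig0 + stats::rnorm(J, 0, step_s0)
    new0 <- lp_s0(prop0)
    new0[abs(prop0) > 60] <- -Inf
    acc0 <- log(stats::runif(J)) < new0 - cur0
    lsig0[acc0] <- prop0[acc0]
    # MH: tau (log scale)
    lp_tau <- function(lt) {
      tv <- exp(lt)
      sum(stats::dnorm(m, m0[j], tv, log = TRUE)) +
        log_dnorm_pos(tv, 5, 10) + lt
    }
    lt <- log(tau)
    ptau <- lt + stats::rnorm(1, 0, step_t)
    acc_t <- abs(ptau) < 60 &&
      log(stats::runif(1)) < lp_tau(ptau) - lp_tau(lt)
    if (acc_t) tau <- exp(ptau)
    # MH: nu (log scale)
    lp_nu <- function(ln) {
      nv <- exp(ln)
      sum(stats::dnorm(lsig, lsig0[j], nv, log = TRUE)) +
        log_dnorm_pos(nv, 5, 10) + ln
    }
    ln <- log(nu)
    pnu <- ln + stats::rnorm(1, 0, step_n)
    acc_n <- abs(pnu) < 60 &&
      log(stats::runif(1)) < lp_nu(pnu) - lp_nu(ln)
    if (acc_n) nu <- exp(pnu)
    # warmup adaptation toward ~40% acceptance
    if (t <= warmup) {
      g <- (t + 10)^-0.6
      step_s <- step_s * exp(g * (acc - 0.44))
      step_s0 <- step_s0 * exp(g * (acc0 - 0.44))
      step_t <- step_t * exp(g * (acc_t - 0.44))
      step_n <- step_n * exp(g * (acc_n - 0.44))
    } else {
      i <- t - warmup
      draws$m0[i, ] <- m0
      draws$sigma0[i, ] <- exp(lsig0)
      draws$tau[i] <- tau
      draws$nu[i] <- nu
    }
  }
  draws
}

# Split-chain potential-scale-reduction diagnostic.
split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat) %/% 2L
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[n + seq_len(n), , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  B <- n * stats::var(mns)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the hierarchical model's posterior
#'
#' Metropolis-within-Gibbs sampler targeting [hier_log_posterior()]:
#' all mean parameters have conjugate normal conditionals and are drawn
#' exactly; the log standard deviations and the two hyper sds use
#' adapted univariate random-walk Metropolis steps. Several chains are
#' run and the split-chain scale-reduction diagnostic is reported for
#' every population-level parameter.
#'
#' @param table an estimation trial table (`subject`, `condition`, `x`,
#'   `response`).
#' @param chains number of chains.
#' @param iter post-warmup draws per chain.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; chain `i` uses `seed + i`.
#' @return a list with `summary` (a `data.frame` keyed by
#'   `condition:x` with posterior mean and 5th/95th percentiles of
#'   `m0` and `sigma0`, plus their R-hats), `hyper` (posterior summary
#'   of `tau` and `nu`), `converged` (all R-hats `< 1.05`), `draws`
#'   (merged post-warmup draws) and `prep` (index structures).
#' @export
hier_sample <- function(table, chains = 4, iter = 500, warmup = 500,
                        seed = 1) {
  prep <- hier_prepare(table)
  runs <- lapply(seq_len(chains), function(i)
    hier_chain(prep, iter, warmup, seed + i))
  J <- length(prep$cells)
  m0_all <- do.call(rbind, lapply(runs, `[[`, "m0"))
  s0_all <- do.call(rbind, lapply(runs, `[[`, "sigma0"))
  tau_all <- unlist(lapply(runs, `[[`, "tau"))
  nu_all <- unlist(lapply(runs, `[[`, "nu"))
  rhat_of <- function(field, col) {
    split_rhat(sapply(runs, function(r)
      if (is.matrix(r[[field]])) r[[field]][, col] else r[[field]]))
  }
  qs <- function(v) stats::quantile(v, c(0.05, 0.95), names = FALSE)
  summ <- data.frame(
    cell = prep$cells, x = prep$x_of_j,
    m0_mean = colMeans(m0_all),
    m0_q05 = apply(m0_all, 2L, function(v) qs(v)[1]),
    m0_q95 = apply(m0_all, 2L, function(v) qs(v)[2]),
    sigma0_mean = colMeans(s0_all),
    sigma0_q05 = apply(s0_all, 2L, function(v) qs(v)[1]),
    sigma0_q95 = apply(s0_all, 2L, function(v) qs(v)[2]),
    rhat_m0 = vapply(seq_len(J), function(c2) rhat_of("m0", c2),
                     numeric(1)),
    rhat_sigma0 = vapply(seq_len(J), function(c2)
      rhat_of("sigma0", c2), numeric(1)))
  rownames(summ) <- NULL
  hyper <- data.frame(
    param = c("tau", "nu"),
    mean = c(mean(tau_all), mean(nu_all)),
    q05 = c(qs(tau_all)[1], qs(nu_all)[1]),
    q95 = c(qs(tau_all)[2], qs(nu_all)[2]),
    rhat = c(rhat_of("tau", 1L), rhat_of("nu", 1L)))
  all_rhat <- c(summ$rhat_m0, summ$rhat_sigma0, hyper$rhat)
  converged <- all(all_rhat < 1.05)
  if (!converged)
    warning("some split-chain R-hats exceed 1.05; summaries may be ",
            "unreliable", call. = FALSE)
  list(summary = summ, hyper = hyper, converged = converged,
       draws = list(m0 = m0_all, sigma0 = s0_all, tau = tau_all,
                    nu = nu_all),
       prep = prep)
}
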