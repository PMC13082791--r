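uniform_problem <- function(w, a, lam = 1, K = 1, n = 256) {
  xs <- seq(0, w, length.out = n)
  allocation_problem(xs, rep(1 / w, n), a = a, lam = lam, K = K)
}

test_that("loss and budget functionals behave as integrals", {
  pr <- uniform_problem(4, a = 1)
  flat <- function(c) fisher_profile(pr$xs, rep(c, length(pr$xs)))
  expect_equal(loss(flat(2), pr), 1 / 2, tolerance = 1e-10)
  pr2 <- uniform_problem(4, a = 2)
  expect_equal(loss(flat(2), pr2), 1 / (4 * 2), tolerance = 1e-10)
  # homogeneity: doubling I halves the loss
  tri <- allocation_problem(pr$xs, pmin(pr$xs, 4 - pr$xs), a = 2)
  expect_equal(loss(flat(2), tri), loss(flat(1), tri) / 2)
  # vanishing information on the support gives infinite loss
  expect_equal(loss(flat(0), pr), Inf)

  # budget: flat K/w^2 profile on width w saturates sqrt(K)
  prof <- single_signal_optimum(prior_spec(0, 10), K = 100)
  expect_equal(constraint_value(prof), 10, tolerance = 1e-10)
  expect_equal(prof$I[1], 1)
  expect_equal(constraint_value(fisher_profile(pr$xs,
                                               rep(0, length(pr$xs)))), 0)
  # sqrt homogeneity: scaling I1 by 4 doubles the budget use
  expect_equal(constraint_value(flat(4)), 2 * constraint_value(flat(1)))
})

test_that("closed forms: optimal n and total information", {
  expect_equal(optimal_n(9, a = 1), 9)
  expect_equal(optimal_n(9, a = 2), 3)
  expect_equal(optimal_n(1, a = 1.37), 1)
  # n follows w^((3-a)/2) exactly
  w <- c(10, 20, 40, 80)
  for (a in 1:2) {
    sl <- stats::coef(stats::lm(log(optimal_n(w, a)) ~ log(w)))[2]
    expect_equal(unname(sl), (3 - a) / 2, tolerance = 1e-12)
  }
  expect_equal(uniform_total_fisher(1, 1), 1)
  expect_equal(uniform_total_fisher(100, 1), 0.01)
  # general solution reduces to the uniform closed form
  for (a in 1:2) {
    pr <- uniform_problem(4, a = a)
    prof <- optimal_total_fisher(pr)
    expect_equal(prof$I[10], uniform_total_fisher(4, a),
                 tolerance = 1e-10)
    expect_equal(prof$n, optimal_n(4, a), tolerance = 1e-10)
  }
  expect_equal(optimal_total_fisher(uniform_problem(4, 1))$I[1], 0.25)
  expect_equal(optimal_total_fisher(uniform_problem(4, 2))$I[1],
               4^(-3 / 2))
})

test_that("imprecision scales as w^(1/2) and w^(3/4)", {
  expect_equal(scaling_exponent(c(20, 40, 60), a = 1), 0.5,
               tolerance = 1e-10)
  expect_equal(scaling_exponent(c(30, 80), a = 2), 0.75,
               tolerance = 1e-10)
  expect_error(scaling_exponent(c(20, 20), a = 1), "distinct")
})

test_that("numerical allocation oracle reproduces the closed forms", {
  for (a in 1:2) {
    # uniform prior
    pr <- uniform_problem(20, a = a)
    bf <- brute_force_allocation(pr)
    cl <- optimal_total_fisher(pr)
    expect_lt(max(abs(bf$n * bf$I / cl$I - 1)), 0.02)
    expect_lt(abs(bf$n / cl$n - 1), 0.02)
    expect_lt(abs(constraint_value(bf) - sqrt(pr$K)), 1e-4)
    # achieved objective no worse than the closed-form candidate
    obj_cl <- loss(fisher_profile(cl$xs, cl$I), pr) + pr$lam * cl$n
    expect_lte(attr(bf, "objective"), obj_cl + 1e-6)

    # triangular prior, compared on the bulk of the support
    xs <- seq(0, 2, length.out = 256)
    tri <- allocation_problem(xs, pmin(xs, 2 - xs), a = a)
    bft <- brute_force_allocation(tri)
    clt <- optimal_total_fisher(tri)
    keep <- tri$pi_x >= 0.05 * max(tri$pi_x)
    expect_lt(max(abs((bft$n * bft$I / clt$I)[keep] - 1)), 0.02)
    expect_lt(abs(constraint_value(bft) - 1), 1e-4)
  }
})

test_that("closed-form allocations dominate random feasible profiles", {
  set.seed(2024)
  for (a in 1:2) {
    pr <- uniform_problem(10, a = a)
    cl <- optimal_total_fisher(pr)
    obj_cl <- loss(fisher_profile(cl$xs, cl$I), pr) + pr$lam * cl$n
    m <- length(pr$xs)
    for (i in 1:200) {
      s <- stats::runif(m, 0.05, 1)
      s <- s * sqrt(pr$K) / trapz(pr$xs, s)     # saturate the budget
      n <- stats::runif(1, 0.1, 10) * cl$n
      obj <- loss(fisher_profile(pr$xs, n * s^2), pr) + pr$lam * n
      expect_gte(obj, obj_cl - 1e-9)
    }
  }
})

test_that("flat single-signal profile is a constrained optimum", {
  # first-order check: feasible budget-preserving perturbations do not
  # reduce the loss
  pr <- uniform_problem(10, a = 1, n = 128)
  prof <- single_signal_optimum(prior_spec(0, 10), K = 1, grid_size = 128)
  base <- loss(fisher_profile(prof$xs, prof$I), pr)
  set.seed(7)
  for (i in 1:25) {
    d <- stats::rnorm(128)
    s <- sqrt(prof$I) * (1 + 1e-4 * (d - mean(d)))
    s <- s * sqrt(1) / trapz(prof$xs, s)
    pert <- loss(fisher_profile(prof$xs, s^2), pr)
    expect_gte(pert, base - 1e-10)
  }
})

test_that("log-constrained signal profile saturates the budget", {
  pf <- log_constrained_single_signal(1, exp(1), K = 1)
  expect_equal(pf$I[1], 1, tolerance = 1e-10)          # 1/x^2 at x = 1
  expect_equal(constraint_value(pf), 1, tolerance = 1e-4)
  expect_equal(pf$I[1] / pf$I[length(pf$I)], exp(2), tolerance = 1e-10)
  pf2 <- log_constrained_single_signal(1, exp(1), K = 2)
  expect_equal(pf2$I / pf$I, rep(2, length(pf$I)))
  expect_error(log_constrained_single_signal(-1, 2), "0 < x0")
})

test_that("log-constrained total information approaches its leading term", {
  out <- log_constrained_total_fisher(100, 1, a = 1)     # h/x_mid = 0.01
  expect_lt(abs(out$ratio - 1), 1e-3)
  # second-order deficit ~ (1/6)(h/x_mid)^2
  for (eps in c(0.05, 0.1)) {
    o <- log_constrained_total_fisher(1, eps, a = 2)
    expect_equal(o$rel_deficit / (eps^2 / 6), 1, tolerance = 0.1)
  }
  # width-scaling of the imprecision at fixed x/x_mid
  slope_for <- function(a) {
    hs <- c(0.05, 0.1, 0.2, 0.3)
    Imid <- vapply(hs, function(h) {
      o <- log_constrained_total_fisher(1, h, a = a)
      idx <- which.min(abs(o$profile$xs - 1))
      o$profile$I[idx]
    }, numeric(1))
    unname(stats::coef(stats::lm(log(1 / sqrt(Imid)) ~ log(2 * hs)))[2])
  }
  expect_equal(slope_for(1), 0.5, tolerance = 0.02)
  expect_equal(slope_for(2), 0.75, tolerance = 0.02)
})
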