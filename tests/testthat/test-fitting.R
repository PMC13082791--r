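test_that("BIC follows its definition", {
  expect_equal(bic(-5, 2, 10), 2 * log(10) + 10)
  expect_equal(bic(0, 0, 50), 0)
  expect_true(all(diff(sapply(0:4, function(k) bic(-10, k, 20))) > 0))
})

test_that("estimation likelihood is additive and anchored", {
  p <- narrow_prior()
  enc <- encoding_spec("linear", 1, 0.5)
  P <- response_pmf_matrix(enc, 3, p)
  tab1 <- data.frame(subject = 1L, condition = "Narrow", x = 60L,
                     response = 62L, half = "first")
  attr(tab1, "priors") <- list(Narrow = p)
  nll1 <- estimation_nll(tab1, 1, 3, 0.5)
  expect_equal(nll1, -log(P["60", "62"]), tolerance = 1e-10)
  # duplicating the table doubles the NLL
  tab2 <- rbind(tab1, tab1)
  attr(tab2, "priors") <- list(Narrow = p)
  expect_equal(estimation_nll(tab2, 1, 3, 0.5), 2 * nll1)
  # out-of-range response is an error, not a drop
  bad <- tab1
  bad$response <- 75L
  attr(bad, "priors") <- list(Narrow = p)
  expect_error(estimation_nll(bad, 1, 3, 0.5), "outside prior range")
})

test_that("true generator parameters dominate perturbed ones", {
  pop <- subject_population(6, nu_median = 1, nu_sdlog = 0,
                            sigma0_median = 3, sigma0_sdlog = 0)
  tab <- gen_estimation(pop, trials_per_condition = 60, seed = 21)
  nll_true <- estimation_nll(tab, 1, 3, 0.5)
  expect_lt(nll_true, estimation_nll(tab, 2, 3, 0.5))
  expect_lt(nll_true, estimation_nll(tab, 1, 3, 1))
  expect_lt(nll_true, estimation_nll(tab, 1, 6, 0.5))
})

test_that("free-exponent fits nest fixed ones and ignore row order", {
  pop <- small_est_pop()
  tab <- gen_estimation(pop, trials_per_condition = 25, seed = 31)
  f_free <- fit_estimation(tab, alpha = "free")
  f_half <- fit_estimation(tab, alpha = 0.5)
  expect_gte(f_free$logL, f_half$logL - 1e-4)
  expect_equal(f_free$k, 3L)
  expect_equal(f_half$k, 2L)
  expect_equal(f_half$bic, 2 * log(nrow(tab)) - 2 * f_half$logL)
  # row order invariance
  perm <- sample(nrow(tab))
  tabp <- tab[perm, ]
  attr(tabp, "priors") <- attr(tab, "priors")
  f_perm <- fit_estimation(tabp, alpha = 0.5)
  expect_equal(f_perm$logL, f_half$logL, tolerance = 1e-6)
})

test_that("individual-parameter estimation fits run and improve fit", {
  pop <- small_est_pop()
  tab <- gen_estimation(pop, trials_per_condition = 20, seed = 41)
  f_ind <- fit_estimation(tab, alpha = 0.5, nu_mode = "individual",
                          sigma0_mode = "individual")
  f_sh <- fit_estimation(tab, alpha = 0.5)
  expect_gte(f_ind$logL, f_sh$logL - 1e-4)
  expect_equal(f_ind$k, 2L * 4L)
  expect_length(f_ind$params$nu, 4L)
  # motor-only model is nested below the full model
  f_m <- fit_estimation(tab, nu_mode = "zero")
  expect_lte(f_m$logL, f_sh$logL + 1e-4)
  expect_equal(f_m$k, 1L)
})

test_that("discrimination likelihood matches the Bernoulli form", {
  # balanced coin-flip table: NLL = n log 2 when the model implies 1/2
  tab <- data.frame(subject = 1L, condition = "Narrow",
                    x_R = rep(50, 10), x_B = rep(50, 10),
                    choice = rep(c("red", "blue"), 5), half = "first")
  attr(tab, "priors") <- discrimination_priors()
  expect_equal(discrimination_nll(tab, 0.22, 0.75, eta = 0),
               10 * log(2), tolerance = 1e-12)
  expect_error(discrimination_nll(
    transform(tab, choice = "r"), 0.22, 0.75), "choices")
})

test_that("pooled discrimination fit recovers nu and eta", {
  tab <- gen_discrimination(small_disc_pop(8), small_disc_pop(8),
                            trials = 150, seed = 51)
  f <- fit_discrimination(tab, alpha = 0.75, lapse = TRUE)
  expect_lt(abs(f$params$eta - 0.05), 0.04)
  expect_lt(abs(f$params$nu - 0.22), 0.05)
  # free alpha on a single condition is not identifiable
  sub <- tab[tab$condition == "Narrow", ]
  attr(sub, "priors") <- attr(tab, "priors")
  expect_error(fit_discrimination(sub, alpha = "free"),
               "not identifiable")
  # per-subject fits return nu_tilde near nu * w^alpha
  ss <- fit_discrimination_subjects(tab)
  sp <- attr(tab, "subject_params")
  m <- merge(ss, sp, by = "subject")
  truth <- m$nu * ifelse(m$condition.x == "Narrow", 30, 80)^0.75
  expect_gt(stats::cor(m$nu_tilde, truth), 0.5)
  expect_lt(stats::median(abs(m$nu_tilde / truth - 1)), 0.25)
})

test_that("magnitude-split probit recovers scale differences", {
  set.seed(61)
  gen_split <- function(n, sc_small, sc_large, thr = 50) {
    xm <- stats::runif(n, 15, 85)
    d <- stats::runif(n, -12, 12)
    x_R <- xm + d / 2
    x_B <- xm - d / 2
    keep <- (x_R < thr & x_B < thr) | (x_R > thr & x_B > thr)
    x_R <- x_R[keep]; x_B <- x_B[keep]
    sc <- ifelse(x_R < thr & x_B < thr, sc_small, sc_large)
    pr <- stats::pnorm((x_R - x_B) / sc)
    data.frame(subject = 1L, condition = "Wide", x_R = x_R, x_B = x_B,
               choice = ifelse(stats::runif(length(pr)) < pr,
                               "red", "blue"))
  }
  tab <- gen_split(6000, 5, 6.5)
  out <- split_magnitude_probit(tab)
  expect_equal(out$scale_large / out$scale_small, 1.3, tolerance = 0.1)
  expect_lt(out$p, 0.05)

  # strata with identical trials cannot be improved by two scales
  base <- gen_split(800, 5, 5)
  mirrored <- base
  mirrored$x_R <- 100 - base$x_B
  mirrored$x_B <- 100 - base$x_R
  tab2 <- rbind(base[base$x_R < 50 & base$x_B < 50, ],
                mirrored[mirrored$x_R > 50 & mirrored$x_B > 50, ])
  out2 <- split_magnitude_probit(tab2)
  expect_lt(out2$LR_chi2, 1e-4)
})

test_that("equal-scale generators yield calibrated LR rejections", {
  set.seed(71)
  pv <- replicate(60, {
    xm <- stats::runif(500, 20, 80)
    d <- stats::runif(500, -10, 10)
    x_R <- xm + d / 2
    x_B <- xm - d / 2
    keep <- (x_R < 50 & x_B < 50) | (x_R > 50 & x_B > 50)
    pr <- stats::pnorm((x_R[keep] - x_B[keep]) / 5)
    tab <- data.frame(subject = 1L, condition = "Wide",
                      x_R = x_R[keep], x_B = x_B[keep],
                      choice = ifelse(stats::runif(length(pr)) < pr,
                                      "red", "blue"))
    split_magnitude_probit(tab)$p
  })
  expect_lt(mean(pv < 0.05), 0.15)
  expect_gt(mean(pv < 0.5), 0.2)
})

test_that("KS matching is rank-based and detects misscaled widths", {
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  out <- ks_match(same, c(30, 30), alpha = 0.75)
  expect_equal(out$D, 0)
  # common rescaling leaves D unchanged
  a <- stats::rlnorm(40, 0, 0.2)
  b <- stats::rlnorm(40, 0.1, 0.2)
  d1 <- ks_match(list(a, b), c(30, 80), 0.75)$D
  d2 <- ks_match(list(10 * a, 10 * b), c(30, 80), 0.75)$D
  expect_equal(d1, d2)
})

test_that("Bayesian model selection responds to evidence", {
  # identical evidences -> 50/50
  lev <- matrix(0, nrow = 12, ncol = 2)
  out <- bms_proportions(lev)
  expect_equal(out$expected_freq, c(0.5, 0.5), tolerance = 1e-8)
  # strong unanimous evidence -> dominant frequency
  lev1 <- cbind(rep(20, 12), rep(0, 12))
  out1 <- bms_proportions(lev1)
  expect_gt(out1$expected_freq[1], 0.9)
  # column permutation permutes the output
  out2 <- bms_proportions(lev1[, 2:1])
  expect_equal(out2$expected_freq, rev(out1$expected_freq),
               tolerance = 1e-8)
  expect_error(bms_proportions(cbind(c(1, NA), c(0, 0))), "finite")
})
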