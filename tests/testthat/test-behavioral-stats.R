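test_that("the five-bin schemes partition each prior exactly", {
  expect_equal(default_bins("Narrow")$ranges,
               rbind(c(50, 52), c(53, 57), c(58, 62), c(63, 67),
                     c(68, 70)))
  expect_equal(default_bins("Medium")$ranges[3, ], c(56, 64))
  for (cn in c("Narrow", "Medium", "Wide")) {
    b <- default_bins(cn)
    p <- estimation_priors()[[cn]]
    covered <- unlist(lapply(1:5, function(i)
      b$ranges[i, 1]:b$ranges[i, 2]))
    expect_identical(sort(covered), as.integer(p$support))
    expect_equal(length(covered), length(unique(covered)))
    # middle bin centered on the prior midpoint
    expect_equal(mean(b$ranges[3, ]), 60)
  }
  expect_error(default_bins("Wider"), "arg")
})

test_that("excursion variance isolates trial-to-trial variability", {
  b <- default_bins("Narrow")
  # all responses equal per number -> zero in every non-empty bin
  tab <- data.frame(x = rep(c(51, 60, 69), each = 3),
                    response = rep(c(55, 61, 70), each = 3))
  ev <- excursion_variance(tab, b)
  expect_true(all(ev$variance[!is.na(ev$variance)] == 0))
  # hand-computed example: excursions {-2, +2}, population variance 4
  tab2 <- data.frame(x = c(60, 60), response = c(58, 62))
  ev2 <- excursion_variance(tab2, b, ddof = 0)
  expect_equal(ev2$variance[3], 4)
  expect_true(is.na(ev2$variance[1]))
  # translation invariance
  tab3 <- tab2
  tab3$response <- tab3$response + 5
  expect_equal(excursion_variance(tab3, b, ddof = 0)$variance[3], 4)
})

test_that("coefficient of variation flags scalar variability", {
  tab <- data.frame(x = c(60, 60), response = c(50, 70))
  cv <- cv_curve(tab, ddof = 0)
  expect_equal(cv$cv, 10 / 60, tolerance = 1e-12)
  expect_equal(cv_curve(data.frame(x = c(55, 55),
                                   response = c(57, 57)))$cv, 0)
  # sd proportional to x gives a flat cv curve
  set.seed(12)
  xs <- rep(seq(30, 90, 5), each = 400)
  resp <- stats::rnorm(length(xs), xs, 0.1 * xs)
  cvs <- cv_curve(data.frame(x = xs, response = resp))
  expect_lt(stats::sd(cvs$cv), 0.015)
  expect_equal(mean(cvs$cv), 0.1, tolerance = 0.1)
})

test_that("relative error scales inversely with the width", {
  perfect <- data.frame(x = c(60, 55), response = c(60, 55))
  expect_equal(relative_error(perfect, 20),
               list(mean_abs_error = 0, ratio = 0))
  one <- data.frame(x = 60, response = 66)
  expect_equal(relative_error(one, 20), list(mean_abs_error = 6,
                                             ratio = 0.3))
  expect_equal(relative_error(one, 40)$ratio, 0.15)
})

test_that("two-point affine extrapolation reproduces the diagnostic", {
  pts <- rbind(c(20, 17.64), c(40, 46.24))
  expect_equal(affine_extrapolate(pts, "width_squared", 60), 93.91,
               tolerance = 1e-3)
  expect_equal(affine_extrapolate(pts, "width", 60), 74.84,
               tolerance = 1e-10)
  # interpolation identity
  expect_equal(affine_extrapolate(pts, "width_squared", 40), 46.24)
  expect_equal(affine_extrapolate(pts, "width", 20), 17.64)
  expect_error(affine_extrapolate(rbind(c(20, 1), c(20, 2)),
                                  "width", 60), "coincident")
})

test_that("variance-versus-width diagnostic separates the generators", {
  # square-root-scaling observer: variance ~ affine in w
  pop_sqrt <- subject_population(6, nu_median = 1, nu_sdlog = 0,
                                 sigma0_median = 3, sigma0_sdlog = 0,
                                 alpha = 0.5)
  # normalization observer: variance ~ affine in w^2
  pop_lin <- subject_population(6, nu_median = 0.14, nu_sdlog = 0,
                                sigma0_median = 3, sigma0_sdlog = 0,
                                alpha = 1)
  rss <- function(tab) {
    v <- sapply(names(estimation_priors()), function(cn) {
      sub <- tab[tab$condition == cn, ]
      ev <- excursion_variance(sub, default_bins(cn))
      stats::weighted.mean(ev$variance, ev$n, na.rm = TRUE)
    })
    w <- c(20, 40, 60)
    c(w = sum(stats::resid(stats::lm(v ~ w))^2),
      w2 = sum(stats::resid(stats::lm(v ~ I(w^2)))^2))
  }
  t_sqrt <- gen_estimation(pop_sqrt, trials_per_condition = 400,
                           seed = 17)
  t_lin <- gen_estimation(pop_lin, trials_per_condition = 400,
                          seed = 18)
  r1 <- rss(t_sqrt)
  r2 <- rss(t_lin)
  expect_lt(r1["w"], r1["w2"])   # sqrt generator: affine in width wins
  expect_lt(r2["w2"], r2["w"])   # normalization generator: reversed
})

test_that("psychometric summaries are calibrated and collapse correctly", {
  # noiseless choices -> all-correct bins away from zero
  nl <- subject_population(2, nu_median = 0, nu_sdlog = 0,
                           lapse_eta = 0)
  tabnl <- gen_discrimination(nl, nl, trials = 200, seed = 3)
  pb <- psychometric_bins(tabnl, normalizer_alpha = 0.75)
  expect_true(all(pb$correct$prop == 1))
  # symmetric generator: P(red) around 0.5 near zero difference
  pops <- lapply(c(16, 16), small_disc_pop)
  tab <- gen_discrimination(pops[[1]], pops[[2]], trials = 200,
                            seed = 13)
  pbs <- psychometric_bins(tab, normalizer_alpha = 0.75)
  for (cn in c("Narrow", "Wide")) {
    sg <- pbs$signed[pbs$signed$condition == cn, ]
    sg <- sg[order(sg$abscissa), ]
    # sigmoid shape: below 1/2 on the left, above on the right,
    # increasing overall
    expect_lt(sg$prop[1], 0.5)
    expect_gt(sg$prop[nrow(sg)], 0.5)
    expect_gt(stats::cor(sg$abscissa, sg$prop), 0.9)
  }
  # collapse is best at the generating exponent
  gaps <- psychometric_collapse(tab, alphas = c(0.5, 0.75, 1))
  expect_lt(gaps["alpha=0.75"], gaps["alpha=0.5"])
  expect_lt(gaps["alpha=0.75"], gaps["alpha=1"])
})

test_that("classical tests match their references", {
  # identical groups: Levene W = 0, p = 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  lt <- levene_test(v, g)
  expect_equal(lt$W, 0)
  expect_equal(lt$p, 1)
  # Fisher exact on a diagonal 10/10 table vs hypergeometric enumeration
  ft <- fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))
  p_exact <- sum(stats::dhyper(c(0, 10), 10, 10, 10))
  expect_equal(ft$p, p_exact, tolerance = 1e-12)
  expect_equal(p_exact, 2 / choose(20, 10), tolerance = 1e-12)
  # Holm step-down on a two-value example
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
})

test_that("half splits are consistent with the full table", {
  pop <- small_est_pop()
  tab <- gen_estimation(pop, trials_per_condition = 40, seed = 19)
  # row counts per half differ by at most one per subject x condition
  cnt <- table(tab$subject, tab$condition, tab$half)
  expect_true(all(abs(cnt[, , "first"] - cnt[, , "second"]) <= 1))
  hs <- half_split(tab, "estimation")
  expect_named(hs, c("Narrow", "Medium", "Wide"), ignore.order = TRUE)
  # a stationary generator rarely produces Holm-significant differences
  sig <- unlist(lapply(hs, function(h) h$p_holm < 0.05))
  expect_lt(mean(sig), 0.2)
  # concatenating halves reproduces the full-table excursion counts
  sub <- tab[tab$condition == "Narrow", ]
  b <- default_bins("Narrow")
  full_n <- excursion_variance(sub, b)$n
  h1 <- excursion_variance(sub[sub$half == "first", ], b)$n
  h2 <- excursion_variance(sub[sub$half == "second", ], b)$n
  expect_equal(full_n, h1 + h2)
})
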