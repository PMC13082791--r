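# Simulated behavioral experiments.
#
# The generators reproduce the statistical structure of the two
# numerosity experiments (and of a risky-choice design) with responses
# produced by the observer model itself, so that every downstream
# analysis is testable without any external data.

#' Subject population specification
#'
#' Inter-subject heterogeneity of the observer parameters: the baseline
#' imprecision `nu` and motor noise `sigma0` are drawn log-normally
#' around configurable medians (noise parameters are positive and
#' right-skewed), while the scaling exponent `alpha` is shared by all
#' subjects, as the theory treats it as a property of the task, not of
#' the individual.
#'
#' @param n_subjects number of subjects.
#' @param nu_median,nu_sdlog median and log-scale sd of the per-subject
#'   baseline imprecision.
#' @param sigma0_median,sigma0_sdlog median and log-scale sd of the
#'   per-subject motor noise (estimation task only).
#' @param alpha shared width-scaling exponent.
#' @param encoding `"linear"` or `"logarithmic"`.
#' @param lapse_eta shared lapse probability (choice tasks only).
#' @return an object of class `subject_population`.
#' @examples
#' subject_population(36)
#' @export
subject_population <- function(n_subjects,
                               nu_median = 1.0, nu_sdlog = 0.2,
                               sigma0_median = 3.0, sigma0_sdlog = 0.2,
                               alpha = 0.5,
                               encoding = c("linear", "logarithmic"),
                               lapse_eta = 0) {
  encoding <- match.arg(encoding)
  stopifnot_scalar(n_subjects, "n_subjects", positive = TRUE)
  if (nu_sdlog < 0 || sigma0_sdlog < 0)
    stop("dispersions must be >= 0", call. = FALSE)
  if (lapse_eta < 0 || lapse_eta > 1)
    stop("'lapse_eta' must be in [0, 1]", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         nu_median = nu_median, nu_sdlog = nu_sdlog,
         sigma0_median = sigma0_median, sigma0_sdlog = sigma0_sdlog,
         alpha = alpha, encoding = encoding, lapse_eta = lapse_eta),
    class = "subject_population"
  )
}

#' Standard study populations
#'
#' The default subject populations of the simulated experiments.
#' Estimation: 36 subjects, median imprecision 1.0 and motor noise 3.0
#' (log-normal, sdlog 0.2), exponent 1/2 — magnitudes matching the
#' variability levels the estimation task elicits. Discrimination:
#' 31 (Narrow) and 32 (Wide) subjects, median imprecision 0.22,
#' exponent 3/4, lapse 0.05; the dispersion is smaller (sdlog 0.1)
#' because the exponent is identified between subject groups, and the
#' group comparison at ~30 subjects per condition resolves it only when
#' individual baselines are reasonably homogeneous.
#'
#' @return `estimation_population()`: one [subject_population()];
#'   `discrimination_populations()`: a list with `Narrow` and `Wide`.
#' @export
estimation_population <- function() {
  subject_population(36, nu_median = 1.0, nu_sdlog = 0.2,
                     sigma0_median = 3.0, sigma0_sdlog = 0.2,
                     alpha = 0.5, encoding = "linear", lapse_eta = 0)
}

#' @rdname estimation_population
#' @export
discrimination_populations <- function() {
  mk <- function(n) subject_population(
    n, nu_median = 0.22, nu_sdlog = 0.1, alpha = 0.75,
    encoding = "linear", lapse_eta = 0.05)
  list(Narrow = mk(31), Wide = mk(32))
}

# Draw per-subject (nu, sigma0) given the population law.
draw_subject_params <- function(pop) {
  nu <- if (pop$nu_median == 0) rep(0, pop$n_subjects) else
    stats::rlnorm(pop$n_subjects, log(pop$nu_median), pop$nu_sdlog)
  sigma0 <- if (pop$sigma0_median == 0) rep(0, pop$n_subjects) else
    stats::rlnorm(pop$n_subjects, log(pop$sigma0_median), pop$sigma0_sdlog)
  data.frame(subject = seq_len(pop$n_subjects), nu = nu, sigma0 = sigma0)
}

#' Simulate the numerosity-estimation experiment
#'
#' Each subject completes every condition. Presented numbers are sampled
#' uniformly over the integers of each condition's prior; responses are
#' drawn from the observer model's exact response distribution
#' ([response_pmf()]) with the subject's `(nu, sigma0)` and the shared
#' exponent. Trials in the first half of each condition are labelled
#' `"first"`, the rest `"second"`.
#'
#' @param pop a [subject_population()].
#' @param priors list of three [prior_spec()] conditions (default the
#'   standard Narrow/Medium/Wide set of [estimation_priors()]).
#' @param trials_per_condition scored trials per condition (default 120).
#' @param seed integer RNG seed; the same seed reproduces the table
#'   exactly.
#' @return a `data.frame` with columns `subject`, `condition`, `x`,
#'   `response`, `half`, plus attributes `priors` and `subject_params`.
#' @examples
#' tab <- gen_estimation(subject_population(2), trials_per_condition = 10)
#' nrow(tab)  # 2 x 3 x 10
#' @export
gen_estimation <- function(pop, priors = estimation_priors(),
                           trials_per_condition = 120, seed = 1234) {
  stopifnot(inherits(pop, "subject_population"))
  if (trials_per_condition < 1)
    stop("'trials_per_condition' must be >= 1", call. = FALSE)
  lapply(priors, function(p) stopifnot(inherits(p, "prior_spec")))
  set.seed(seed)
  subj <- draw_subject_params(pop)
  half_lab <- ifelse(seq_len(trials_per_condition) <=
                       trials_per_condition / 2, "first", "second")
  rows <- vector("list", pop$n_subjects * length(priors))
  k <- 0L
  for (s in seq_len(pop$n_subjects)) {
    enc <- encoding_spec(pop$encoding, subj$nu[s], pop$alpha)
    for (cn in names(priors)) {
      p <- priors[[cn]]
      P <- response_pmf_matrix(enc, subj$sigma0[s], p)
      x <- sample(p$support, trials_per_condition, replace = TRUE)
      resp <- vapply(x, function(xi) {
        sample(p$support, 1L, prob = P[as.character(xi), ])
      }, integer(1))
      k <- k + 1L
      rows[[k]] <- data.frame(subject = s, condition = cn, x = x,
                              response = resp, half = half_lab)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "priors") <- priors
  attr(out, "subject_params") <- subj
  out
}

#' Simulate the average-discrimination experiment
#'
#' Each subject experiences a single condition. On each trial five red
#' and five blue integers are drawn uniformly from the condition's
#' prior; the choice is Bernoulli with the observer's choice probability
#' ([choice_probability()]) evaluated at the two averages. In the
#' noiseless, lapse-free limit the larger average is always chosen, with
#' exact ties resolved as "red".
#'
#' @param pop_narrow,pop_wide [subject_population()]s for the two
#'   conditions (their `sigma0` settings are unused here).
#' @param priors list of two [prior_spec()]s (default
#'   [discrimination_priors()]).
#' @param trials scored trials per subject (default 200).
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `subject`, `condition`,
#'   `r1..r5`, `b1..b5`, `x_R`, `x_B`, `choice`, `half`, plus attributes
#'   `priors` and `subject_params`. Subject ids are unique across the
#'   two conditions.
#' @examples
#' pop <- subject_population(2, nu_median = 0.22, alpha = 0.75,
#'                           lapse_eta = 0.05)
#' tab <- gen_discrimination(pop, pop, trials = 5)
#' @export
gen_discrimination <- function(pop_narrow, pop_wide,
                               priors = discrimination_priors(),
                               trials = 200, seed = 1234) {
  stopifnot(inherits(pop_narrow, "subject_population"),
            inherits(pop_wide, "subject_population"))
  if (trials < 1) stop("'trials' must be >= 1", call. = FALSE)
  set.seed(seed)
  half_lab <- ifelse(seq_len(trials) <= trials / 2, "first", "second")
  pops <- list(pop_narrow, pop_wide)
  rows <- list()
  params <- list()
  offset <- 0L
  for (ci in seq_along(priors)) {
    pop <- pops[[ci]]
    p <- priors[[ci]]
    cn <- names(priors)[ci]
    subj <- draw_subject_params(pop)
    subj$subject <- subj$subject + offset
    subj$condition <- cn
    params[[ci]] <- subj
    for (s in seq_len(pop$n_subjects)) {
      enc <- encoding_spec(pop$encoding, subj$nu[s], pop$alpha)
      reds <- matrix(sample(p$support, 5L * trials, replace = TRUE), trials)
      blues <- matrix(sample(p$support, 5L * trials, replace = TRUE), trials)
      x_R <- rowMeans(reds)
      x_B <- rowMeans(blues)
      if (enc$nu > 0) {
        pr <- choice_probability(x_B, x_R, enc, p$width, eta = pop$lapse_eta)
      } else {
        pr <- ifelse(x_R >= x_B, 1, 0)          # ties to 'red'
        pr <- (1 - pop$lapse_eta) * pr + pop$lapse_eta / 2
      }
      choice <- ifelse(stats::runif(trials) < pr, "red", "blue")
      df <- data.frame(subject = subj$subject[s], condition = cn,
                       reds, blues, x_R = x_R, x_B = x_B,
                       choice = choice, half = half_lab)
      names(df)[3:12] <- c(paste0("r", 1:5), paste0("b", 1:5))
      rows[[length(rows) + 1L]] <- df
    }
    offset <- offset + pop$n_subjects
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "priors") <- priors
  attr(out, "subject_params") <- do.call(rbind, params)
  out
}

#' Simulate a risky-choice experiment
#'
#' Choices between a certain amount `C` and a lottery paying `X` with
#' probability 1/2 (zero otherwise). The observer compares the encoded
#' lottery expected value `p X` with the certain amount, with an
#' additive bias on the certain option, so
#' `P(lottery) = (1 - eta) Phi((mu(pX) - mu(C) - bias)/(sqrt(2) nu w^alpha)) + eta/2`.
#' Lottery amounts are uniform over the condition's prior range and
#' certain amounts uniform over its half (the scale of `p X`).
#'
#' @param pop a [subject_population()]; each subject is assigned to one
#'   condition, alternating.
#' @param priors list of two [prior_spec()]s for the lottery amounts
#'   (default widths 8 and 24 around a common scale).
#' @param trials trials per subject.
#' @param bias additive bias toward the certain option.
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `subject`, `condition`, `C`, `X`,
#'   `p`, `choice`, plus attributes.
#' @examples
#' pop <- subject_population(4, nu_median = 0.2, alpha = 0.75,
#'                           lapse_eta = 0.05)
#' gen_risky(pop, trials = 3)[1:3, ]
#' @export
gen_risky <- function(pop,
                      priors = list(Narrow = prior_spec(16, 24, "Narrow"),
                                    Wide = prior_spec(8, 32, "Wide")),
                      trials = 100, bias = 0.295, seed = 1234) {
  stopifnot(inherits(pop, "subject_population"))
  if (trials < 1) stop("'trials' must be >= 1", call. = FALSE)
  set.seed(seed)
  subj <- draw_subject_params(pop)
  cond_of <- names(priors)[(subj$subject - 1L) %% length(priors) + 1L]
  rows <- vector("list", pop$n_subjects)
  for (s in seq_len(pop$n_subjects)) {
    cn <- cond_of[s]
    p <- priors[[cn]]
    enc <- encoding_spec(pop$encoding, subj$nu[s], pop$alpha)
    X <- stats::runif(trials, p$x_min, p$x_max)
    C <- stats::runif(trials, p$x_min / 2, p$x_max / 2)
    pr <- choice_probability(C, X / 2, enc, p$width,
                             eta = pop$lapse_eta, bias = bias)
    choice <- ifelse(stats::runif(trials) < pr, "lottery", "certain")
    rows[[s]] <- data.frame(subject = s, condition = cn, C = C, X = X,
                            p = 0.5, choice = choice)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "priors") <- priors
  attr(out, "subject_params") <- cbind(subj, condition = cond_of)
  attr(out, "bias") <- bias
  out
}

#' Trial reward of the estimation task
#'
#' The per-trial payoff added to the performance bonus: 10 cents minus
#' the squared estimation error over 600.
#'
#' @param x presented number.
#' @param response the subject's estimate.
#' @return dollar amount `0.10 - (response - x)^2 / 600`, vectorized.
#' @examples
#' reward_estimation(60, 66)  # 0.04
#' @export
reward_estimation <- function(x, response) {
  0.10 - (response - x)^2 / 600
}

#' Write / read a trial table as CSV
#'
#' Plain-CSV persistence with the standard headers; `read_trials`
#' restores the `priors` attribute when the conditions are recognized.
#'
#' @param table a trial table from one of the generators.
#' @param path file path.
#' @param task `"estimation"`, `"discrimination"` or `"risky"`.
#' @return `read_trials` returns the `data.frame`.
#' @export
write_trials <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, task = c("estimation", "discrimination",
                                       "risky")) {
  task <- match.arg(task)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "priors") <- switch(task,
    estimation = estimation_priors(),
    discrimination = discrimination_priors(),
    risky = NULL)
  out
}
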