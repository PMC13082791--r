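# Shared small fixtures, built in code.

narrow_prior <- function() prior_spec(50, 70, "Narrow")

small_est_pop <- function(...) {
  subject_population(4, nu_median = 1, nu_sdlog = 0.2,
                     sigma0_median = 3, sigma0_sdlog = 0.2,
                     alpha = 0.5, ...)
}

small_disc_pop <- function(n = 4, ...) {
  subject_population(n, nu_median = 0.22, nu_sdlog = 0.1, alpha = 0.75,
                     lapse_eta = 0.05, ...)
}

# A tiny estimation table for hand checks.
toy_est_table <- function() {
  tab <- data.frame(subject = 1L, condition = "Narrow",
                    x = c(60L, 60L, 55L, 55L),
                    response = c(58L, 62L, 55L, 57L),
                    half = c("first", "first", "second", "second"))
  attr(tab, "priors") <- estimation_priors()["Narrow"]
  tab
}
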