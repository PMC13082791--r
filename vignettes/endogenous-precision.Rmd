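---
title: "Endogenous precision: model, allocation problem, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous precision: model, allocation problem, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoprec)
```

## The scientific question

How precisely the brain represents a magnitude — here, the numerosity of
a briefly shown array, or the running average of a number stream — is
not a fixed property of the observer. If representational precision is
allocated rationally, it should depend on the *context* (the prior
distribution from which stimuli are drawn) and on the *task* (what the
representation will be used for). `endoprec` implements a complete,
testable pipeline around this idea: an encoding–decoding observer model
whose noise scales with the prior width, the resource-allocation problem
whose solution predicts *how* it should scale, simulators for the three
behavioral designs, maximum-likelihood model comparison, a descriptive
battery, and a hierarchical Bayesian model of estimation variability.

## The observer model

A stimulus $x$ elicits an internal representation
$r \mid x \sim N\!\big(\mu(x),\, \nu^2 w^{2\alpha}\big)$, where $\mu$ is
the transducer (identity, or $\log x$ for a compressed number line),
$w$ is the width of the uniform prior of the current condition, $\nu$
sets the baseline imprecision, and $\alpha \ge 0$ governs how the
imprecision grows with the prior width. The Fisher information is
$I(x) = \big(\mu'(x) / (\nu w^\alpha)\big)^2$; $1/\sqrt{I}$ is the local
imprecision scale.

* **Estimation.** The observer reports the posterior mean
  $x^*(r) = E[x \mid r]$ under the discrete uniform prior, then a motor
  stage adds Gaussian noise of sd $\sigma_0$, truncated to the slider
  range and rounded to the nearest integer (`response_pmf()`). The
  decoding prior is the *discrete* uniform over the range's integers —
  matching how stimuli are actually drawn; the efficient-coding algebra
  below uses continuous densities. At these ranges the two give nearly
  identical predictions.
* **Discrimination / risky choice.** Two values are encoded
  independently and the larger decoded value is chosen, giving
  $P(\text{red}) = (1-\eta)\,\Phi\!\big(\tfrac{\mu(x_R)-\mu(x_B)-\text{bias}}
  {\sqrt2\,\nu w^\alpha}\big) + \eta/2$ with lapse probability $\eta$
  (`choice_probability()`). The bias term is used only for the
  risky-choice variant, where the two options (a certain amount and a
  lottery's expected value) are not symmetric.
* **Range-normalization baseline.** `range_normalized_response()`
  implements the non-Bayesian alternative in which the number is mapped
  to the unit interval and read with constant noise; its response
  variance is $\sigma_0^2 + \tilde\nu^2 w^2$ — affine in the *squared*
  width, which is exactly what the affine-extrapolation diagnostic
  (`affine_extrapolate()`) is designed to refute or confirm.

### Numerical choices

The estimation likelihood integrates over $r$ by fixed quadrature (201
nodes spanning $\mu(x) \pm 6\nu w^\alpha$ in `response_pmf()`;
deterministic likelihoods keep the optimizer's surface smooth).
`response_pmf_matrix()` evaluates the same integral for all stimuli of
a condition on one shared grid whose spacing resolves both the
representation sd and the narrowest rounding cell; the two routes agree
to $10^{-6}$ and are cross-checked in the test suite. Posterior weights
are accumulated in log space, so the readout saturates cleanly at the
range bounds instead of producing NaN. Boundary rounding cells are
$[x_{\min}, x_{\min}+\tfrac12]$ and $[x_{\max}-\tfrac12, x_{\max}]$
after truncation, so every draw maps to an in-range integer, as a
bounded slider enforces. With $\sigma_0 = 0$ the motor stage is a point
mass at the rounded decoded value.

## The resource-allocation problem

The observer accumulates $n$ i.i.d. encoding signals. One signal's
Fisher information obeys the budget
$\int \sqrt{I_1(x)}\,dx \le \sqrt K$, each signal costs $\lambda$, and
total information is $n I_1(x)$. The observer minimizes

$$L_a[nI_1] + \lambda n, \qquad
  L_a[I] = \int \frac{\pi(x)^a}{I(x)}\,dx,$$

with $a = 1$ for a squared-error (estimation) objective and $a = 2$ for
a discrimination objective. The solution (`optimal_total_fisher()`)
is $I(x) = \pi(x)^{2a/3}\big/\sqrt{\theta \int \pi^{a/3}}$ with
$\theta = \lambda/K$, and on a uniform prior of width $w$
(`uniform_total_fisher()`):

$$I = \frac{1}{\sqrt\theta\, w} \;(a=1), \qquad
  I = \frac{1}{\sqrt\theta\, w^{3/2}} \;(a=2),$$

so the imprecision $1/\sqrt I$ scales as $w^{1/2}$ in estimation and
$w^{3/4}$ in discrimination — the package's two headline exponents
(`scaling_exponent()`). The optimal signal count is
$n = w^{(3-a)/2}/\sqrt{\lambda K}$, treated as continuous throughout.
If $n$ is fixed at one instead, the budget alone forces
$I_1 = K/w^2$ (`single_signal_optimum()`): imprecision proportional to
$w$, the same for every task — the pattern the endogenous-$n$ solution
replaces.

When the signal is additionally constrained to the $1/x^2$ information
profile of a logarithmic transducer, the budget pins the level
(`log_constrained_single_signal()`), and re-optimizing $n$ gives an
exact total-information formula whose leading term in the relative
half-width $h/x_{\rm mid}$ is
$\sqrt{K/\lambda}\,(2h)^{-(1+a)/2}(x_{\rm mid}/x)^2$, with a relative
second-order deficit of $\tfrac16 (h/x_{\rm mid})^2$
(`log_constrained_total_fisher()` returns both and their ratio). The
width-scaling exponents are unchanged.

### The numerical oracle

`brute_force_allocation()` solves the allocation problem with no
recourse to the closed forms: it optimizes $s(x) = \sqrt{I_1(x)}$ on a
512-point grid (the budget is linear in $s$ and active at the optimum,
so the scale of $s$ is fixed by saturation), profiles the signal count
out analytically ($n^* = \sqrt{L/\lambda}$), and runs BFGS with an
analytic gradient from a *flat* start. On uniform and triangular priors
it reproduces the closed forms to better than $10^{-5}$ relative on the
bulk of the support; comparisons exclude grid points with density below
5% of the maximum, where both solutions tend to zero and a ratio is
uninformative.

## What the simulators emulate — and what they do not

`gen_estimation()` reproduces the estimation design: three
uniform-prior conditions [50, 70], [40, 80], [30, 90] with a common
midpoint of 60; 120 scored trials per condition; 36 subjects, all of
whom experience every condition; responses drawn from the observer's
exact response distribution. `gen_discrimination()` reproduces the
between-subject discrimination design: priors [35, 65] (31 subjects)
and [10, 90] (32 subjects), 200 scored trials of five red and five blue
integers each. `gen_risky()` emulates a certain-versus-lottery design
with $p = \tfrac12$ and narrow/wide amount priors; the amount
distributions are not published for the reference dataset, so the
defaults (lottery amounts on [16, 24] and [8, 32], certain amounts on
the halved ranges, bias 0.295) are a synthetic stand-in.

Heterogeneity. Per-subject $\nu$ and $\sigma_0$ are drawn log-normally
around configurable medians — noise parameters are positive and
right-skewed, and no population law is published. Defaults:

* Estimation: $\nu$ median 1.0, $\sigma_0$ median 3.0, both sdlog 0.2,
  $\alpha = \tfrac12$, linear encoding. These magnitudes produce
  response SDs rising from roughly 4 to 8 across the three widths, the
  scale the task elicits. The design is within-subject, so subject
  heterogeneity does not contaminate the width-scaling exponent.
* Discrimination: $\nu$ median 0.22 (matching the elicited psychometric
  slopes), $\alpha = \tfrac34$, lapse 0.05, sdlog 0.1. Here the design
  is *between*-subject: the exponent is identified by the ratio of
  typical imprecision across two independent groups of ~31 subjects,
  whose median-sampling noise grows with the population dispersion. At
  sdlog 0.1 the design resolves the exponent to a few hundredths while
  retaining genuine inter-subject variability (which the
  distribution-matching analysis below requires).

What passing tests on these simulations do **not** show: that real
subjects obey the model. The generators share the observer model with
the fitted likelihoods, so the recovery and model-comparison tests are
internal-consistency checks (can the analysis identify what generated
the data at study scale?), not evidence about human behavior. Sequence
effects, learning, number-format differences between tasks, and
dot-rendering artifacts are deliberately outside the generators' scope.

## Fitting and model comparison

`fit_estimation()` fits $(\nu, \sigma_0, \alpha)$ by bounded
quasi-Newton (L-BFGS-B on log noise scales; $\alpha \in [0, 1.5]$) from
a fixed 10-point start grid, with the exponent fixed or free, the noise
parameters shared or per-subject (per-subject structures decouple given
$\alpha$ and are fit independently; a free shared exponent is profiled
by an outer univariate search), and a motor-noise-only variant
($\nu = 0$). `fit_discrimination()` fits $(\nu, \alpha, \eta)$ (and
optionally a bias) to pooled choice data; per-subject, single-condition
data identify only $\tilde\nu = \nu w^\alpha$, which
`fit_discrimination_subjects()` returns. Comparison is by BIC
($k \ln N - 2\log L$); `estimation_bic_grid()` and
`discrimination_bic_grid()` tabulate the standard model grids. The
lapse bound $\eta \le 0.5$ avoids the reflection non-identifiability of
lapse rates above one half; $\tilde\nu$ is bounded in
$[10^{-6}, 50]$.

Three further analyses mirror the battery around the main fits:
`split_magnitude_probit()` (a lapse probit whose noise scale may differ
for small- versus large-magnitude trials, tested by a likelihood ratio
against $\chi^2_1$ with no boundary correction — the scales are
interior parameters), `ks_match()` (two-sample Kolmogorov–Smirnov
equality of $\tilde\nu / w^\alpha$ across conditions), and
`bms_proportions()` (random-effects Bayesian model selection: a
variational Dirichlet over model frequencies from per-subject
evidences, approximated as $-\mathrm{BIC}/2$, iterated to $10^{-6}$).

## The hierarchical variability model

`hier_sample()` estimates, per condition $c$ and number $x$, a
population mean $m_{0c}(x)$ and sd $\sigma_{0c}(x)$, with subject-level
means $m_{sc}(x) \sim N(m_{0c}(x), \tau^2)$ and log-sds
$\ln \sigma_{sc}(x) \sim N(\ln \sigma_{0c}(x), \nu_h^2)$, and
hyperpriors $m_{0c}(x) \sim N(x, 20^2)$,
$\sigma_{0c}(x) \sim N_+(7, 7^2)$, $\tau, \nu_h \sim N_+(5, 10^2)$
(truncated at zero with explicit renormalization). The sampler is a
Metropolis-within-Gibbs scheme targeting `hier_log_posterior()` (which
is unit-tested against a term-by-term oracle): all means have conjugate
normal conditionals and are drawn exactly; log-sds and the two hyper
sds take adapted random-walk steps. Numbers a subject never saw
contribute no subject-level term. The log-sd domain is truncated at
$|\ln \sigma| \le 60$ — without it, prior draws with a large $\nu_h$
push subject sds into floating-point underflow (the usual funnel); the
truncation is immaterial at the scale of any summary. Convergence is
monitored by split-chain scale reduction ($\hat R < 1.05$), and
summaries are still emitted, with a warning, when it fails. The desk
default is 4 chains of 500 draws after 500 warmup iterations; larger
presets are a single argument away. Calibration uses data generated
from the model's own prior (`gen_hierarchical()`, default 12 subjects
per condition, every integer of the three standard priors, 3 trials per
number), under which 90% posterior intervals have their nominal
frequentist coverage over repeated simulation.

## Design choices where the design was open

* Decoding prior discrete, allocation algebra continuous (see above).
* Ties in the noiseless discrimination limit resolve to "red";
  documented, and only reachable when $\nu = 0$ and $\eta = 0$.
* Excursion variances default to the sample variance (denominator
  $n-1$) for data analysis; the population variance is available via
  `ddof = 0`. Levene tests are mean-centered by default
  (median-centering, the Brown–Forsythe variant, via an argument).
* Psychometric bin edges are equal-count quantile bins and binomial
  CIs use the normal approximation; the source analyses do not publish
  their edges or CI method.
* `half` labels split each subject-condition block at the trial-index
  midpoint, mirroring the stability analysis.
* Rewards (`reward_estimation()`: $0.10 - (\hat x - x)^2/600$ dollars)
  are generated for completeness but never used in fitting.

## Problem sizes

The shipped analyses run at the study's own scale where that is cheap
(12,960 estimation trials; 12,600 discrimination trials; 50 replicates
of the distribution-matching analysis) and at a documented desk scale
where it is not: the allocation oracle uses 512-point grids (sub-percent
agreement with the closed forms), and the hierarchical model runs
4 × 500/500 chains on a 12-subjects-per-condition simulation.

## Known limitations

* The estimation fitter does not offer every mixed shared/individual
  parameter combination (e.g. individual $\nu$ with shared $\sigma_0$),
  whose joint likelihood no longer decouples by subject; the offered
  structures cover the analyses the package ships.
* The observer treats a discrimination trial through the two stream
  averages only; no within-trial accumulation over the ten numbers is
  modelled.
* Real-data ingestion is a CSV path (`read_trials()`) with the
  documented headers; cleaning rules for any particular external
  dataset are the user's responsibility.
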