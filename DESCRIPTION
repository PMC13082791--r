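Package: endoprec
Title: Endogenous Precision of Numerosity Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the precision of internal magnitude
    representations adapts to the stimulus context.  Implements a Bayesian
    observer model in which the encoding noise scales with the width of the
    stimulus prior, solves the resource-rational efficient-coding problem
    (a Fisher-information budget per signal plus a per-signal cost) whose
    solutions predict square-root and three-quarter power scaling of the
    imprecision in estimation and discrimination tasks, simulates the
    corresponding behavioral experiments, fits the observer models by
    maximum likelihood with BIC-based model comparison, and provides the
    descriptive battery (binned excursion variances, psychometric
    summaries, distribution-matching tests) and a hierarchical
    mixed-effects model of estimation responses sampled by MCMC.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
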