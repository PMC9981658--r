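Package: cyclephase
Title: Cycle-Phase-Aware Analysis of Daily Athlete Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal daily wellness and training
    monitoring of female athletes in relation to menstrual-cycle and
    hormonal-contraception phases. Provides calendar-based cycle
    segmentation and six-phase classification of natural cycles,
    pill-regimen phase assignment for combined oral contraception, a
    per-athlete top-quintile enrichment test (chi-square goodness of fit
    against a uniform phase distribution with Pearson-residual phase
    flags), a Bayesian proportional-odds model of 1-10 Likert scores
    versus menstrual status fitted by Metropolis MCMC with Gelman-Rubin
    diagnostics and highest-density intervals, symptom-by-phase
    tabulation, a Spearman rank-correlation screen, and a configurable
    synthetic cohort generator used to validate every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), MASS, jsonlite, withr
Config/testthat/edition: 3
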