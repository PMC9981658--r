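# cyclephase

Cycle-phase-aware analysis of daily athlete-monitoring data.

Standard athlete monitoring collects daily 1-10 Likert self-reports
(sleep quality, fitness, mood, training performance), Borg CR10 perceived
exertion, sleep timing, menstrual symptoms and occasional coach
evaluations. For female athletes these measures can vary with the
menstrual cycle (MC) or the hormonal-contraception (HC) pill regimen, and
ignoring that structure biases how "readiness" scores are read.
`cyclephase` is a reusable, base-R implementation of a cycle-phase-aware
analysis pipeline for sports scientists and biostatisticians working with
such longitudinal cohorts.

## What it computes

* **Phase classification.** Bleeding calendars are segmented into cycles
  (an onset is a bleeding day preceded by 14 bleed-free days). Natural
  cycles get six phases anchored on the calendar-predicted ovulation day
  `P.O = L - 14` (fixed-luteal rule): menses, mid/late follicular,
  early/mid luteal, premenstrual. Pill users get a withdrawal `pause` plus
  one or two active phases on a tiled 21+7 pack grid; a binary
  menses/no-menses scheme covers everyone. Salivary estradiol and
  progesterone sampled at nominal cycle days 8/14/24 (+/-2) cross-check
  the calendar phases.
* **Top-quintile enrichment.** Per athlete, a day is "top" when its score
  strictly exceeds her own empirical 0.8-quantile (order statistic
  `ceiling(0.8 n)`). Top-day counts, normalised by phase exposure and
  athlete, are tested against the discrete uniform `1/k` with a
  chi-square goodness-of-fit statistic `sum((O - E)^2 / E)` on `k - 1`
  df; if significant at alpha = 0.05, Pearson residuals
  `(O_p - E_p) / sqrt(E_p)` flag phases beyond +/-1.96 (alpha = 0.05) or
  +/-1.64 (alpha = 0.1). Symptoms are summed per phase.
* **Proportional-odds menses model.** Pooled across athletes,
  `P(Y <= j | x) = logit^{-1}(theta_j - beta x)` with `x = 1` on menses
  days, fitted by Metropolis MCMC (flat priors, 4 chains, 1,000 burn-in +
  1,000 draws), convergence by split-chain Gelman-Rubin `Rhat < 1.1`,
  posteriors reported as means with 75% highest-density intervals.
* **Spearman screen.** Pairwise-complete rank correlations across all
  monitored variables with per-pair significance at alpha = 0.05
  (permutation p-values for sparse cells such as coach scores).
* **Synthetic cohorts.** A generator with the cohort's statistical
  structure (12 athletes, ~4-5 cycles, 78% response, phase-dependent
  latent Likert shifts and symptom rates, lognormal hormones) validates
  every stage without any external data.

## Worked example

```r
library(cyclephase)

cohort <- generate_cohort(synthetic_config(seed = 1))
#> Synthetic cohort: 12 athletes, 1433 daily records, 177 hormone samples

run_enrichment(cohort$daily, cohort$profiles, scheme = "mc6")
#> Top-quintile phase enrichment (mc6 scheme, k = 6)
#>   sleep_quality     chi2 =   9.36, df = 5, p = 0.0957
#>   fitness           chi2 =  62.75, df = 5, p = 3.28e-12 *
#>     flags: menses (under_05), late_follicular (over_05), premenstrual (under_05)
#>   mood              chi2 =  46.89, df = 5, p = 5.98e-09 *
#>     flags: menses (under_05), late_follicular (over_05), premenstrual (under_05)
#>   self_performance  chi2 =  40.81, df = 5, p = 1.02e-07 *
#>     flags: menses (under_05), late_follicular (over_05), premenstrual (under_05)

phases <- assign_phases(cohort$daily, cohort$profiles, "binary")
days <- merge(cohort$daily, phases[c("athlete_id", "date", "phase")])
fit <- fit_proportional_odds(days$self_performance, days$phase == "menses",
                             mcmc_config(seed = 2))
fit
#> Proportional-odds menses model: 1313 days, 10 score categories
#>   chains: 4 x 1000 draws (burn-in 1000)
#>   beta (menses): -1.283  [75% HDI -1.437, -1.119]
#>   max Rhat: 1.008; acceptance: 0.23-0.26
```

Reading the output: the significant chi-square tests say top-quintile
self-evaluations are not uniform across the six cycle phases; the
residual flags localise the deviation - rarer top scores in menses and
premenstrual phases, more frequent around the late follicular phase
(here, the effects the synthetic preset injected). Sleep quality shows no
significant omnibus effect, so its residuals are not read. The negative
menses coefficient of the ordinal model (posterior mean -1.28, 75% HDI
[-1.44, -1.12]) shifts the self-rated performance distribution towards
lower scores on bleeding days; `probability_table(fit)` gives the
per-score probabilities by status.

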