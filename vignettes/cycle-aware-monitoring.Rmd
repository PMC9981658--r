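---
title: "Cycle-phase-aware analysis of daily athlete monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-phase-aware analysis of daily athlete monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cyclephase` analyses longitudinal daily self-report data from female
athletes - 1-10 Likert scores for sleep quality, fitness, mood and
training performance, Borg CR10 perceived exertion, sleep timing,
menstrual symptoms, and sparse coach evaluations - in relation to
menstrual-cycle (MC) and hormonal-contraception (HC) phases. This
vignette explains the statistical machinery, the choices behind its
defaults, and what the synthetic validation cohort does and does not
establish.

```{r setup}
library(cyclephase)
```

## Phase classification

### Natural cycles

A cycle onset is a bleeding day preceded by at least 14 bleed-free days;
requiring a clear window keeps a one-day gap in a self-reported multi-day
menses from splitting a cycle in two. Complete cycles run from one onset
to the day before the next; trailing days after the last observed onset
cannot be assigned a cycle length and are excluded, as are athletes who
never declare bleeding (amenorrhea).

Within a complete cycle of length $L$, ovulation is predicted by the
fixed-luteal calendar rule $\hat{o} = L - 14$ (clamped to fall after
menses). Six phases are then laid out with this precedence -
menses > premenstrual > late follicular > early luteal > mid follicular >
mid luteal:

* **menses**: days $1..b$ (bleed length $b$);
* **premenstrual**: the final 4 days;
* **late follicular**: the 4 days ending at $\hat{o}$;
* **early luteal**: the 4 days after $\hat{o}$;
* **mid follicular** / **mid luteal**: the remaining pre-/post-ovulatory
  days.

Every cycle day receives exactly one label (the partition is tested
exhaustively over $21 \le L \le 45$). The window widths are genuinely
open choices: they were fixed, once, so that for a canonical 28-day,
5-day-bleed cycle the nominal salivary sampling days land in their target
phases - day 8 in mid follicular, day 14 in late follicular, day 24 in
mid luteal. For short cycles the fixed-luteal rule necessarily pulls
ovulation towards menses, and those nominal anchors cannot all hold; the
windows simply shift with $\hat{o}$. Cycles under 21 days trigger a
warning and proportional rescaling of the windows rather than rejection,
since irregular cycles are part of field data. All widths and the luteal
constant are exposed through `phase_windows()`.

### Pill regimens and the binary scheme

Combined-pill users are labelled on a tiled pack grid (default 21 active
+ 7 pause days), with regimen day 1 the first pause day. The pause is one
phase; a monophasic pack has a single active phase, while bi-/triphasic
packs are split into `phase1`/`phase2` after active day 10 - a default
standing in for the true dose-change boundary, overridable per athlete.
The pack grid is anchored on withdrawal bleeding: regimen day 1 is placed
`hc_bleed_offset` (default 1) days before the earliest bleeding day
observed anywhere on the grid, which is robust to a missed questionnaire
on any single withdrawal day.

The `binary` scheme labels a day `menses` exactly when bleeding was
declared, for all athletes alike; withdrawal bleeding counts. It is the
common scale for pooled analyses (the ordinal model, coach scores).

### Hormone cross-check

Salivary estradiol and progesterone samples taken at nominal cycle days
8/14/24 (&plusmn;2) summarise into per-phase means;
`check_hormone_ordering()` verifies the expected pattern - progesterone
peaking mid luteal, estradiol peaking late follicular, both lowest mid
follicular - and marks checks `indeterminate` when a phase is missing.
Ties fail (the peak must be strict).

## The top-quintile enrichment statistic

For one athlete and one variable, a day is *top-flagged* when its score
strictly exceeds the athlete's own empirical 0.8-quantile, taken as the
$\lceil 0.8 n \rceil$-th order statistic of her non-missing values. The
strict inequality plus order statistic is the one convention that can
never flag more than 20% of days under the heavy ties of 1-10 Likert
data; with ties it typically flags 10-15%. Fewer than 5 usable days skips
the athlete-variable pair with a warning.

Counts are then normalised "by phase length and by athlete": per athlete
and phase the top-day *rate* (flags / observed days) is computed, rates
are averaged over athletes, and the averages are rescaled to sum to the
raw number of top days. This makes the observed vector invariant to
unequal phase exposure (an athlete followed for five cycles does not
dominate one followed for three) while keeping the total on the count
scale. The unnormalised variant is available (`normalize = FALSE`) for
sensitivity analysis. Whether athletes or athlete-cycles are the
averaging unit is not identifiable from the method description; athletes
are the default unit here.

The observed vector $O$ is tested against the discrete uniform $1/k$
($k$ phases): $E_p = \sum_p O_p / k$,
$\chi^2 = \sum_p (O_p - E_p)^2 / E_p$ on $k - 1$ degrees of freedom.
When - and only when - the omnibus test is significant at $\alpha=0.05$,
the Pearson residuals $r_p = (O_p - E_p)/\sqrt{E_p}$ are read: $|r_p| >
1.96$ flags the phase at $\alpha=0.05$ (`over_05`/`under_05`), $|r_p| >
1.64$ at $\alpha=0.1$. No multiple-testing correction is applied across
variables by default, matching the analysis the statistic implements.

Because each athlete's flag total is fixed by her own quantile threshold,
the statistic is slightly conservative relative to the nominal
$\chi^2_{k-1}$ reference: on null cohorts (no phase effects) the measured
type-I error at $\alpha=0.05$ is ~3-4% rather than 5%. The acceptance
suite verifies it stays within 3-7% over 3,000 simulated cohorts.

Symptoms are summarised separately as raw per-phase sums
(`symptom_sums()`), with set semantics within a day and no exposure
normalisation - mirroring how declared-symptom counts are usually
reported.

## The proportional-odds menses model

Pooled across athletes, a 1-10 score $Y$ on a day with menstrual status
$x \in \{0, 1\}$ follows the cumulative-logit model

$$P(Y \le j \mid x) = \operatorname{logit}^{-1}(\theta_j - \beta x),
\qquad \theta_1 < \dots < \theta_{J-1},$$

so a negative $\beta$ shifts probability mass towards low scores on
menses days. Days with missing outcome are dropped listwise; athlete
identity does not enter the model (days are pooled). Scores are mapped to
categories by their observed distinct values, which handles CR10
half-points without special cases.

Fitting is by MCMC with flat priors on the ordered-cutpoint region: 4
chains, 1,000 burn-in iterations, 1,000 retained draws. The sampler is a
joint random-walk Metropolis whose proposal covariance is the inverse
likelihood curvature at the posterior mode (found by BFGS on an
order-preserving reparameterisation), scaled by $2.38^2/d$; a global
scale factor adapts towards 25% acceptance during burn-in only, and 5
sweeps are made per retained draw. This design was chosen over
component-wise updates because adjacent ordered cutpoints are strongly
coupled: component-wise walks mixed too slowly to pass the
$\hat{R} < 1.1$ convergence requirement reliably, while the joint
curvature-matched proposal reaches $\hat{R} \approx 1.01$-$1.03$ at the
same cost. Proposals breaking the cutpoint ordering have zero prior mass
and are rejected, so every retained draw is strictly ordered.

Convergence is monitored by the split-chain Gelman-Rubin factor
(`rhat()`); rank normalisation is deliberately not applied, keeping the
classical form of the diagnostic. Posterior summaries are means with 75%
highest-density intervals, computed by the narrowest-sorted-window method
(earliest window on ties) - adequate because the marginals here are
unimodal. `probability_table()` reports $P(Y = j \mid x)$ per category
and status; each status column sums to one draw by draw. Parameter
recovery (bias, HDI coverage) is verified in the acceptance suite on data
simulated from the model itself at $n = 800$, $\beta \in \{-1, 0, 1\}$.

## The correlation screen

`spearman_matrix()` computes pairwise-complete Spearman correlations:
average-tie ranks, then the Pearson correlation of ranks. P-values use
the large-sample t approximation, except that cells with fewer than 30
complete pairs switch to a seeded permutation test (10,000 permutations)
- relevant for sparse coach evaluations. Cells with fewer than 4 pairs or
a constant variable are indeterminate rather than zero. Significance is
reported at raw $\alpha = 0.05$, uncorrected, with per-cell $n$ alongside
so the reader can judge. The symptom variable is the daily count of
distinct declared symptoms. Repeated-measures structure is ignored by
design - this is a screen, not an inference engine.

## The synthetic cohort

Real cohorts of this kind are not publicly deposited, so the package
ships a generator (`generate_cohort()`) whose defaults are the study
conditions every statistical claim is tested under: 6 cycling + 1
amenorrheic + 5 pill-using athletes, 150 follow-up days (~4-5 cycles of
28 &plusmn; 2 days, truncated to 21-36), 78% daily response, ~10.6%
coach-evaluation days.

Scores follow a latent-Gaussian model - baseline 6 + athlete effect
(SD 1) + phase effect + noise (SD 1.5) - rounded and clipped to 1..10.
The default phase effects (`paperlike_effect_preset()`) encode the
qualitative pattern the analyses are meant to detect: +1.5 latent points
in the late follicular phase (mood, fitness, performance), -1.5 in
menses, smaller premenstrual deficits, a premenstrual-only dip for sleep
quality, and for pill users a pause deficit with a small phase2 boost.
RPE is generated independently of phase, emulating a load measure that
tracks the training program rather than the cycle. Symptom probabilities
peak in menses/premenstrual phases and in the pill pause
(`paperlike_symptom_rates()`); hormone draws are lognormal with moments
matched to the per-phase means/SDs in `default_hormone_params()`.
Withdrawal bleeding is placed on pause days 2-5 so the binary scheme is
exercised in both groups.

What passing tests on this cohort show: the pipeline detects effects of
the injected kind and size at the cohort's scale, holds its nominal size
when effects are absent, and recovers its own model's parameters. What
they do not show: anything about real athletes' values, robustness to
informative missingness (the generator's missingness is completely at
random; real non-response need not be), anovulatory or otherwise
miscalendared cycles, or symptom vocabularies beyond the seeded list.

## Numerical and testing choices

* Problem sizes: acceptance checks use 3,000 null cohorts (size), 500
  effect cohorts (recovery), 100 ordinal fits at $n=800$ (calibration),
  100 seeds for the hormone-ordering check, and 200 random instances per
  oracle-equivalence check (tolerance $10^{-10}$, likelihood
  $10^{-12}$).
* All randomness is confined with an internal seed-preserving wrapper,
  so library calls never disturb a user's RNG stream and every fit,
  screen and cohort is exactly reproducible from its seed.
* Degenerate inputs fail loudly and early: out-of-range Likert cells
  name their row and field; all-identical scores (unidentifiable
  cutpoints), single chains, empty status groups and zero-exposure
  phases are errors, not NaNs.
* `bedtime` is encoded as minutes after noon so late-night values stay
  monotone (22:00 &lt; 01:00); a wrap-around clock would corrupt rank
  correlations.

## Known limitations

* Ovulation is calendar-predicted, not measured; all six-phase
  inferences inherit that approximation.
* The multiphasic pill split (active day 10) is a stand-in default
  whenever true pack composition is unknown.
* The ordinal model pools days across athletes without random effects;
  with strong between-athlete heterogeneity its $\beta$ mixes within-
  and between-athlete contrasts.
* The enrichment test's mild conservatism (see above) is inherent to
  per-athlete quantile thresholds; exact calibration would require a
  permutation reference, which is out of scope.
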