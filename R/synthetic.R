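# Synthetic monitoring-cohort generator.
#
# Emulates the statistical structure the analyses assume: a small elite
# cohort (six natural-cycle athletes, one amenorrheic, five combined-pill
# users) followed daily for ~150 days (~4-5 cycles), a ~78% daily response
# rate, sparse coach evaluations, phase-dependent latent shifts in 1-10
# Likert scores, phase-dependent symptom probabilities, and salivary
# hormone draws at nominal cycle days 8/14/24 +/- 2. Scores come from a
# latent-Gaussian model (baseline + athlete effect + phase effect + noise)
# discretised to 1..10, so the quintile and ordinal analyses both remain
# mildly misspecified for it - as they would be for real data.

#' Default probability weights over symptom labels
#'
#' @return Named numeric vector of draw weights (normalised internally).
#' @export
default_symptom_mix <- function() {
  c("digestive troubles" = 0.16, "cramps" = 0.12, "headaches" = 0.11,
    "fatigue" = 0.15, "back pain" = 0.10, "bloating" = 0.10,
    "breast tenderness" = 0.08, "mood swings" = 0.08, "acne" = 0.05,
    "insomnia" = 0.05)
}

#' Phase-dependent latent Likert shifts emulating the reported pattern
#'
#' Positive shifts for mood, fitness and self-rated performance around
#' mid-cycle (late follicular / early luteal), negative shifts in menses
#' and premenstrual phases, a premenstrual dip for sleep quality only, and
#' for pill users a performance dip in the withdrawal pause with a small
#' phase2 boost. Magnitudes are tunable defaults in latent Likert points,
#' not empirical estimates.
#'
#' @return Named list: variable -> named vector of per-phase latent shifts.
#' @export
paperlike_effect_preset <- function() {
  list(
    sleep_quality = c(premenstrual = -1.25),
    fitness = c(late_follicular = 1.5, early_luteal = 0.5,
                menses = -1.5, premenstrual = -0.75),
    mood = c(late_follicular = 1.5, menses = -1.5, premenstrual = -0.75),
    self_performance = c(late_follicular = 1.5, early_luteal = 0.75,
                         mid_follicular = 0.5, menses = -1.5,
                         premenstrual = -0.5, pause = -1.0, phase2 = 0.5)
  )
}

#' Phase-dependent daily symptom probabilities
#'
#' Elevated around menses/premenstrual (natural cycles) and the pill
#' withdrawal pause, lowest in the late follicular phase.
#'
#' @return Named numeric vector of per-day symptom probabilities by phase.
#' @export
paperlike_symptom_rates <- function() {
  c(menses = 0.45, premenstrual = 0.35, mid_luteal = 0.25,
    late_follicular = 0.08, mid_follicular = 0.12, early_luteal = 0.12,
    pause = 0.45, phase1 = 0.12, phase2 = 0.12)
}

#' Lognormal hormone parameters per group and nominal sampling day
#'
#' Salivary estradiol and progesterone (pg/mL) means and SDs per nominal
#' sampling day; draws are lognormal with moments matched to these values
#' (positive support and right skew typical of salivary assays).
#'
#' @return Data.frame: `group`, `nominal_day`, `hormone`, `mean`, `sd`.
#' @export
default_hormone_params <- function() {
  # pill users: days 8 and 14 both fall in phase1 and share its parameters
  data.frame(
    group = rep(c("natural_mc", "hc_user"), c(6, 6)),
    nominal_day = c(8, 14, 24, 8, 14, 24, 8, 14, 24, 8, 14, 24),
    hormone = c(rep("estradiol", 3), rep("progesterone", 3),
                rep("estradiol", 3), rep("progesterone", 3)),
    mean = c(2.5, 6.9, 6.0, 38.1, 42.8, 81.85, 1.6, 1.6, 1.8, 20.4, 20.4, 29.6),
    sd = c(1.5, 4.2, 3.8, 31.3, 56.9, 35.7, 0.3, 0.3, 0.9, 7.6, 7.6, 10.9),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the monitored cohort: 6 natural-cycle athletes plus one
#' amenorrheic and 5 combined-pill users, 150 follow-up days (about 4-5
#' cycles of ~28 +/- 2 days), a 78% daily response rate and sparse
#' (~10.6%) coach evaluations coupled to the athlete's self-rated
#' performance.
#'
#' @param n_mc_athletes Cycling natural-cycle athletes.
#' @param n_amenorrheic Natural-cycle athletes who never bleed.
#' @param n_hc_athletes Combined-pill users.
#' @param follow_up_days Follow-up length in days.
#' @param start_date First calendar day of follow-up.
#' @param cycle_length_mean,cycle_length_sd,cycle_length_range Truncated
#'   normal cycle-length distribution (days).
#' @param bleed_length_mean,bleed_length_sd,bleed_length_range Truncated
#'   normal menses-length distribution (days).
#' @param response_rate Daily probability that a questionnaire is filled.
#' @param baseline Named latent baselines of the four Likert variables.
#' @param athlete_sd SD of per-athlete-per-variable latent baselines.
#' @param noise_sd SD of day-level latent noise.
#' @param phase_effects Variable -> per-phase latent shifts (default
#'   [paperlike_effect_preset()]; an empty list gives a null cohort).
#' @param symptom_base_rate Daily symptom probability outside listed phases.
#' @param symptom_rates Per-phase symptom probabilities (default
#'   [paperlike_symptom_rates()]; `NULL` uses the base rate everywhere).
#' @param symptom_mix Draw weights over symptom labels.
#' @param rpe_mean,rpe_sd Latent RPE distribution - independent of phase by
#'   construction, emulating a load measure driven by the training program.
#' @param bedtime_mean,bedtime_sd Bedtime (minutes after noon).
#' @param bedtime_sleep_slope Hours of sleep lost per hour of later bedtime.
#' @param hormone_params See [default_hormone_params()].
#' @param coach_rate Daily probability of a coach evaluation.
#' @param coach_coupling Latent correlation between coach and self scores.
#' @param hc_pill_types Pill composition of each pill user.
#' @param hc_active_days,hc_pause_days Pack regimen (21/7 by default).
#' @param hc_bleed_days Pause days on which withdrawal bleeding occurs.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mc_athletes = 6, n_amenorrheic = 1,
                             n_hc_athletes = 5, follow_up_days = 150,
                             start_date = as.Date("2021-02-14"),
                             cycle_length_mean = 28, cycle_length_sd = 2,
                             cycle_length_range = c(21, 36),
                             bleed_length_mean = 5, bleed_length_sd = 1,
                             bleed_length_range = c(2, 8),
                             response_rate = 0.78,
                             baseline = c(sleep_quality = 6, fitness = 6,
                                          mood = 6, self_performance = 6),
                             athlete_sd = 1, noise_sd = 1.5,
                             phase_effects = paperlike_effect_preset(),
                             symptom_base_rate = 0.15,
                             symptom_rates = paperlike_symptom_rates(),
                             symptom_mix = default_symptom_mix(),
                             rpe_mean = 4, rpe_sd = 1.5,
                             bedtime_mean = 600, bedtime_sd = 45,
                             bedtime_sleep_slope = -0.5,
                             hormone_params = default_hormone_params(),
                             coach_rate = 0.106, coach_coupling = 0.6,
                             hc_pill_types = c("monophasic", "biphasic",
                                               "biphasic", "biphasic",
                                               "triphasic"),
                             hc_active_days = 21, hc_pause_days = 7,
                             hc_bleed_days = 2:5, seed = 20210214L) {
  stopifnot(n_mc_athletes >= 0, n_amenorrheic >= 0, n_hc_athletes >= 0,
            follow_up_days >= 1, cycle_length_mean >= 21,
            response_rate >= 0 && response_rate <= 1,
            coach_rate >= 0 && coach_rate <= 1,
            symptom_base_rate >= 0 && symptom_base_rate <= 1,
            is.null(symptom_rates) ||
              all(symptom_rates >= 0 & symptom_rates <= 1),
            length(hc_pill_types) >= n_hc_athletes)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: %d cycling + %d amenorrheic + ",
                     "%d pill users, %d days, response %.0f%%, seed %d\n"),
              x$n_mc_athletes, x$n_amenorrheic, x$n_hc_athletes,
              x$follow_up_days, 100 * x$response_rate, x$seed))
  invisible(x)
}

.draw_cycles <- function(cf) {
  lens <- integer()
  repeat {
    L <- round(rnorm_trunc(1, cf$cycle_length_mean, cf$cycle_length_sd,
                           cf$cycle_length_range[1] - 0.49,
                           cf$cycle_length_range[2] + 0.49))
    lens <- c(lens, as.integer(L))
    if (length(lens) == 1) {
      offset <- sample.int(lens[1], 1) - 1L  # days already elapsed at start
    }
    if (sum(lens) - offset >= cf$follow_up_days) break
  }
  bl <- round(rnorm_trunc(length(lens), cf$bleed_length_mean, cf$bleed_length_sd,
                          cf$bleed_length_range[1] - 0.49,
                          cf$bleed_length_range[2] + 0.49))
  list(lens = lens, bleeds = pmin(as.integer(bl), lens - 15L), offset = offset)
}

.hormone_value <- function(cf, group, nominal_day, hormone) {
  hp <- cf$hormone_params
  row <- hp[hp$group == group & hp$nominal_day == nominal_day &
              hp$hormone == hormone, ]
  stopifnot(nrow(row) == 1)
  pars <- lnorm_params(row$mean, row$sd)
  rlnorm(1, pars$meanlog, pars$sdlog)
}

.symptom_string <- function(cf, n_days_symptomatic) {
  mix <- cf$symptom_mix / sum(cf$symptom_mix)
  vapply(seq_len(n_days_symptomatic), function(i) {
    k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    paste(sort(sample(names(mix), k, prob = mix)), collapse = ";")
  }, character(1))
}

.generate_athlete <- function(cf, id, kind, pill = "none") {
  FU <- cf$follow_up_days
  dates <- cf$start_date + seq_len(FU) - 1L
  phase <- rep(NA_character_, FU)
  cycle_day <- rep(NA_integer_, FU)
  bleeding <- rep(FALSE, FU)
  hsamp <- NULL
  if (kind == "cycling") {
    cyc <- .draw_cycles(cf)
    starts <- 1L - cyc$offset + c(0L, cumsum(cyc$lens))[seq_along(cyc$lens)]
    for (i in seq_along(cyc$lens)) {
      L <- cyc$lens[i]
      b <- cyc$bleeds[i]
      po <- predict_ovulation(L, b)
      g <- starts[i]:(starts[i] + L - 1L)
      sel <- g >= 1 & g <= FU
      if (!any(sel)) next
      cd <- (g - starts[i] + 1L)[sel]
      phase[g[sel]] <- as.character(classify_mc_phase(cd, L, b, po))
      cycle_day[g[sel]] <- cd
      bleeding[g[sel]] <- cd <= b
      for (nom in c(8L, 14L, 24L)) {
        cds <- nom + sample(-2:2, 1)
        gday <- starts[i] + cds - 1L
        if (cds >= 1 && cds <= L && gday >= 1 && gday <= FU) {
          hsamp <- rbind(hsamp, data.frame(
            athlete_id = id, date = dates[gday], cycle_day = cds,
            nominal_day = nom,
            estradiol = .hormone_value(cf, "natural_mc", nom, "estradiol"),
            progesterone = .hormone_value(cf, "natural_mc", nom, "progesterone"),
            stringsAsFactors = FALSE))
        }
      }
    }
  } else if (kind == "hc") {
    pack <- cf$hc_active_days + cf$hc_pause_days
    offset <- sample.int(pack, 1) - 1L  # regimen days elapsed at start
    rd <- (seq_len(FU) - 1L + offset) %% pack + 1L
    phase <- as.character(classify_hc_phase(rd, pill, cf$hc_active_days,
                                            cf$hc_pause_days))
    cycle_day <- rd
    bleeding <- rd %in% cf$hc_bleed_days
    pack_starts <- seq(1L - offset, FU, by = pack)
    for (ps in pack_starts) {
      for (nom in c(8L, 14L, 24L)) {
        cds <- nom + sample(-2:2, 1)
        gday <- ps + cds - 1L
        if (cds >= 1 && cds <= pack && gday >= 1 && gday <= FU) {
          hsamp <- rbind(hsamp, data.frame(
            athlete_id = id, date = dates[gday], cycle_day = cds,
            nominal_day = nom,
            estradiol = .hormone_value(cf, "hc_user", nom, "estradiol"),
            progesterone = .hormone_value(cf, "hc_user", nom, "progesterone"),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  # latent scores: baseline + athlete effect + phase effect + noise
  vars <- names(cf$baseline)
  ath_eff <- rnorm(length(vars), 0, cf$athlete_sd)
  names(ath_eff) <- vars
  scores <- list()
  latent_perf <- NULL
  for (v in vars) {
    eff <- cf$phase_effects[[v]]
    sh <- if (is.null(eff)) rep(0, FU) else {
      s <- unname(eff[phase])
      ifelse(is.na(s), 0, s)
    }
    latent <- cf$baseline[[v]] + ath_eff[[v]] + sh + rnorm(FU, 0, cf$noise_sd)
    if (v == "self_performance") latent_perf <- latent
    scores[[v]] <- as.integer(pmin(10, pmax(1, round(latent))))
  }
  rpe <- as.integer(pmin(10, pmax(0, round(cf$rpe_mean + rnorm(1, 0, 0.5) +
                                             rnorm(FU, 0, cf$rpe_sd)))))
  bedtime <- round(rnorm(FU, cf$bedtime_mean, cf$bedtime_sd))
  sleep_duration <- round(pmax(3, 8 + cf$bedtime_sleep_slope *
                                 (bedtime - cf$bedtime_mean) / 60 +
                                 rnorm(FU, 0, 0.6)), 1)
  rate <- if (is.null(cf$symptom_rates)) {
    rep(cf$symptom_base_rate, FU)
  } else {
    r <- unname(cf$symptom_rates[phase])
    ifelse(is.na(r), cf$symptom_base_rate, r)
  }
  has_sym <- rbinom(FU, 1, rate) == 1
  symptoms <- rep("", FU)
  symptoms[has_sym] <- .symptom_string(cf, sum(has_sym))
  p_pain <- pmin(1, 0.06 + 0.08 * has_sym)
  painful <- rbinom(FU, 1, p_pain) == 1
  pain <- integer(FU)
  pain[painful] <- pmin(10L, 1L + rpois(sum(painful), 2))
  mu_perf <- cf$baseline[["self_performance"]] + ath_eff[["self_performance"]]
  coach_latent <- mu_perf + cf$coach_coupling * (latent_perf - mu_perf) +
    sqrt(1 - cf$coach_coupling^2) * rnorm(FU, 0, cf$noise_sd)
  coach <- as.integer(pmin(10, pmax(1, round(coach_latent))))
  coach[rbinom(FU, 1, cf$coach_rate) != 1] <- NA_integer_
  responded <- rbinom(FU, 1, cf$response_rate) == 1
  daily <- data.frame(
    athlete_id = id, date = dates, bleeding = bleeding,
    sleep_quality = scores$sleep_quality, fitness = scores$fitness,
    mood = scores$mood, self_performance = scores$self_performance,
    rpe = as.numeric(rpe), sleep_duration = sleep_duration,
    bedtime = as.numeric(bedtime), symptoms = symptoms,
    pain_intensity = pain, coach_performance = coach,
    stringsAsFactors = FALSE
  )[responded, ]
  rownames(daily) <- NULL
  truth <- data.frame(athlete_id = id, date = dates, phase = phase,
                      cycle_day = cycle_day, bleeding = bleeding,
                      responded = responded, stringsAsFactors = FALSE)
  list(daily = daily, truth = truth, hormones = hsamp)
}

#' Generate a synthetic monitoring cohort
#'
#' Draws athlete calendars (truncated-normal cycle lengths for cycling
#' athletes; tiled 21+7 pill regimens with withdrawal bleeding on pause
#' days for pill users), latent-Gaussian Likert scores with phase effects,
#' phase-independent RPE, coupled bedtime/sleep duration, phase-dependent
#' symptoms, sparse coach scores coupled to self-rated performance, and
#' lognormal hormone samples at nominal days 8/14/24 +/- 2. Each
#' athlete-day is observed with probability `response_rate`. Fully
#' reproducible under `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: a list with `profiles`,
#'   `daily`, `hormones`, `truth` (per-day generative phases, including
#'   non-responded days) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    profiles <- daily <- truth <- hormones <- NULL
    add <- function(id, kind, grp, pill, act, pau) {
      a <- .generate_athlete(config, id, kind, pill)
      profiles <<- rbind(profiles, data.frame(
        athlete_id = id, group = grp, pill_type = pill,
        active_days = act, pause_days = pau, stringsAsFactors = FALSE))
      daily <<- rbind(daily, a$daily)
      truth <<- rbind(truth, a$truth)
      hormones <<- rbind(hormones, a$hormones)
    }
    for (i in seq_len(config$n_mc_athletes)) {
      add(sprintf("MC%02d", i), "cycling", "natural_mc", "none",
          NA_integer_, NA_integer_)
    }
    for (i in seq_len(config$n_amenorrheic)) {
      add(sprintf("AM%02d", i), "amenorrheic", "natural_mc", "none",
          NA_integer_, NA_integer_)
    }
    for (i in seq_len(config$n_hc_athletes)) {
      add(sprintf("HC%02d", i), "hc", "hc_user", config$hc_pill_types[i],
          config$hc_active_days, config$hc_pause_days)
    }
    structure(list(profiles = profiles, daily = daily,
                   hormones = hormones, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' Generate a null cohort (no phase effects)
#'
#' Same generative process as [generate_cohort()] with all phase effects
#' removed and a phase-constant symptom rate, so scores and symptoms are
#' independent of phase. Used for type-I-error calibration of the
#' enrichment test and null checks of the ordinal model.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort`.
#' @export
null_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$phase_effects <- list()
  config$symptom_rates <- NULL
  generate_cohort(config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d athletes, %d daily records, %d hormone samples\n",
              nrow(x$profiles), nrow(x$daily),
              if (is.null(x$hormones)) 0L else nrow(x$hormones)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `athletes.csv`, `daily.csv` and `hormones.csv` in the interchange
#' formats of the readers; output is byte-identical for identical
#' config + seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_athletes_csv(cohort$profiles, file.path(dir, "athletes.csv"))
  write_daily_csv(cohort$daily, file.path(dir, "daily.csv"))
  if (!is.null(cohort$hormones)) {
    write_hormones_csv(cohort$hormones, file.path(dir, "hormones.csv"))
  }
  invisible(dir)
}
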