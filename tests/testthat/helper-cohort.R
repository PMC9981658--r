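# Shared fixtures, all generated in code.

quick_config <- function(...) {
  args <- list(n_mc_athletes = 3, n_amenorrheic = 0, n_hc_athletes = 2,
               follow_up_days = 90, seed = 42L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# A tiny hand-written daily data.frame (internal representation).
make_daily <- function(athlete_id, dates, bleeding = FALSE, ...) {
  n <- length(dates)
  out <- data.frame(athlete_id = athlete_id, date = dates,
                    bleeding = rep_len(bleeding, n),
                    sleep_quality = NA_integer_, fitness = NA_integer_,
                    mood = NA_integer_, self_performance = NA_integer_,
                    rpe = NA_real_, sleep_duration = NA_real_,
                    bedtime = NA_real_, symptoms = "",
                    pain_intensity = NA_integer_,
                    coach_performance = NA_integer_,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], n)
  out
}

# Simulate proportional-odds data with uniform categories at x = 0.
sim_po_data <- function(n, beta, J = 10, seed = 1) {
  with_seed(seed, {
    x <- rep(0:1, length.out = n)
    th <- qlogis(seq_len(J - 1) / J)
    cum <- vapply(x, function(xx) plogis(th - beta * xx), numeric(J - 1))
    pr <- rbind(cum, 1) - rbind(0, cum)
    y <- vapply(seq_len(n), function(i) sample.int(J, 1, prob = pr[, i]),
                integer(1))
    list(y = y, x = x, theta = th)
  })
}
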