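# Brute-force quantile-threshold oracle: the smallest observed value q such
# that at most 20% of days strictly exceed q, found by scanning all values.
oracle_top_flags <- function(v, prob = 0.8) {
  q <- sort(v)[ceiling(prob * length(v))]
  as.integer(v > q)
}

test_that("top-quintile binarisation uses the strict order-statistic rule", {
  expect_equal(which(binarize_top_quintile(1:10) == 1L), c(9L, 10L))
  expect_true(all(binarize_top_quintile(rep(7, 20)) == 0L))
  v <- c(rep(5, 9), 10)
  expect_equal(which(binarize_top_quintile(v) == 1L), 10L)
  expect_warning(out <- binarize_top_quintile(c(1, 2, 3, 4)), "skipped")
  expect_null(out)
  # missing days are excluded from the threshold but stay aligned
  v2 <- c(1:10, NA)
  b <- binarize_top_quintile(v2)
  expect_true(is.na(b[11]))
  expect_equal(sum(b, na.rm = TRUE), 2L)
})

test_that("binarisation matches the brute-force oracle on random Likert data", {
  with_seed(2718, {
    for (rep in 1:60) {
      v <- sample(1:10, sample(5:60, 1), replace = TRUE)
      expect_equal(binarize_top_quintile(v), oracle_top_flags(v))
      expect_lte(mean(binarize_top_quintile(v)), 0.2)
    }
  })
})

test_that("normalised counts are exposure-invariant and preserve the top total", {
  ph <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  ind <- rep(c(1, 0), 10)
  o <- normalized_phase_counts(ind, ph, "x")
  expect_equal(unname(o), c(5, 5))
  expect_equal(sum(o), sum(ind))

  # all top days inside one phase
  ind2 <- as.integer(ph == "a") * rep(c(1, 0), each = 5, times = 2)
  o2 <- normalized_phase_counts(ind2, ph, "x")
  expect_equal(unname(o2), c(5, 0))

  # two athletes with unequal exposure but identical per-phase rates give
  # the single-athlete answer up to the total rescaling
  ph3 <- factor(c(rep("a", 4), rep("b", 8), rep("a", 8), rep("b", 16)))
  ind3 <- c(rep(c(1, 0, 0, 0), 1), rep(c(1, 0), 4),        # athlete 1: 25%, 50%
            rep(c(1, 0, 0, 0), 2), rep(c(1, 0), 8))        # athlete 2: same rates
  ath3 <- rep(c("p", "q"), c(12, 24))
  o3 <- normalized_phase_counts(ind3, ph3, ath3)
  expect_equal(unname(o3 / sum(o3)), c(0.25, 0.5) / 0.75)

  expect_error(normalized_phase_counts(ind, factor(ph, levels = c("a", "b", "c")), "x"),
               "phase: c")
})

test_that("chi-square GOF reproduces hand-computed statistics", {
  g <- chisq_uniform_gof(c(10, 10, 10, 10, 10, 10))
  expect_equal(g$chi2, 0)
  expect_equal(g$p_value, 1)
  g2 <- chisq_uniform_gof(c(20, 10, 10, 10, 5, 5))
  expect_equal(g2$chi2, 15)
  expect_equal(g2$df, 5L)
  expect_equal(g2$p_value, 0.010362, tolerance = 1e-4)
  expect_equal(chisq_uniform_gof(c(30, 30))$chi2, 0)
  expect_error(chisq_uniform_gof(c(5), k = 1), "k = 2")
})

test_that("chi-square is relabel-invariant and zero iff uniform", {
  with_seed(5, {
    for (rep in 1:25) {
      k <- sample(2:6, 1)
      o <- rpois(k, 20) + 1
      g <- chisq_uniform_gof(o)
      gp <- chisq_uniform_gof(sample(o))
      expect_equal(g$chi2, gp$chi2)
      expect_equal(g$chi2 == 0, all(o == o[1]))
    }
  })
})

test_that("residual flags follow the printed critical values and the gate", {
  rf <- residual_flags(c(20, 10, 10), expected = rep(10, 3))
  expect_equal(rf$residuals[1], (20 - 10) / sqrt(10))
  expect_identical(unname(rf$flags[1]), "over_05")

  # threshold bands: 1.64 < |r| <= 1.96 is the 10% flag
  o <- 10 + c(-1.8, 1.0, 3.2, -2.5) * sqrt(10)
  rf2 <- residual_flags(o, expected = rep(10, 4))
  expect_identical(unname(rf2$flags), c("under_10", "none", "over_05", "under_05"))

  # residual reading is gated on omnibus significance
  rf3 <- residual_flags(c(20, 10, 10), expected = rep(10, 3), gate_p = 0.2)
  expect_true(all(rf3$flags == "none"))
  expect_true(rf3$gated)

  # weighted residual sum is the count balance, zero after normalisation
  ph <- factor(rep(c("a", "b", "c"), times = c(12, 20, 30)))
  ind <- with_seed(77, as.integer(runif(62) < 0.2))
  o4 <- normalized_phase_counts(ind, ph, "x")
  g4 <- chisq_uniform_gof(o4)
  rf4 <- residual_flags(o4, g4$expected)
  expect_equal(sum(rf4$residuals * sqrt(g4$expected)), 0, tolerance = 1e-10)
})

test_that("symptom sums count set-unique symptoms per phase", {
  dates <- as.Date("2021-03-01") + 0:4
  rec <- make_daily("A1", dates,
                    symptoms = c("cramps;headaches", "cramps", "", "cramps;cramps",
                                 "headaches"))
  phases <- data.frame(athlete_id = "A1", date = dates,
                       phase = factor(c("menses", "menses", "pause", "pause", "pause"),
                                      levels = c("menses", "pause")))
  s <- symptom_sums(rec, phases)
  expect_equal(s$counts["menses", "cramps"], 2)
  expect_equal(s$counts["pause", "cramps"], 1)   # duplicate within day counts once
  expect_equal(s$counts["menses", "headaches"], 1)
  expect_equal(unname(s$totals), c(3, 2))

  none <- symptom_sums(make_daily("A1", dates, symptoms = ""), phases)
  expect_equal(sum(none$totals), 0)
})

test_that("a strong late-follicular boost is recovered end to end", {
  cf <- quick_config(seed = 101L, n_mc_athletes = 6,
                     phase_effects = list(mood = c(late_follicular = 2.5,
                                                   menses = -2.5)),
                     follow_up_days = 140)
  co <- generate_cohort(cf)
  e <- suppressWarnings(run_enrichment(co$daily, co$profiles, "mc6",
                                       variables = "mood"))
  r <- e$results$mood
  expect_lt(r$p_value, 0.05)
  expect_identical(unname(r$flags["late_follicular"]), "over_05")
  expect_match(unname(r$flags["menses"]), "under")
  expect_equal(sum(r$observed), r$total_top)
})

test_that("athletes lacking a variable are dropped from that variable only", {
  cf <- quick_config(seed = 5L)
  co <- generate_cohort(cf)
  co$daily$mood[co$daily$athlete_id == "MC01"] <- NA
  e <- suppressWarnings(run_enrichment(co$daily, co$profiles, "mc6",
                                       variables = c("mood", "fitness")))
  expect_lt(e$results$mood$n_athletes, e$results$fitness$n_athletes)
})

test_that("the binary scheme pools all athletes for sparse coach scores", {
  co <- generate_cohort(quick_config(seed = 9L, follow_up_days = 120))
  e <- suppressWarnings(run_enrichment(co$daily, co$profiles, "binary",
                                       variables = "coach_performance", min_n = 5))
  r <- e$results$coach_performance
  expect_equal(r$k, 2L)
  expect_equal(r$df, 1L)
  expect_true(all(names(r$observed) %in% binary_phases()))
})
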