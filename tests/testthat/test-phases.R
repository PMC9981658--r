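# Brute-force oracle for onset detection: scan every bleeding day and check
# the preceding 14 days directly.
oracle_onsets <- function(dates, bleeding, clear = 14) {
  bd <- dates[bleeding]
  bd[vapply(bd, function(d) !any(bd %in% (d - seq_len(clear))), logical(1))]
}

test_that("segment_cycles matches the brute-force onset scan on random calendars", {
  with_seed(314, {
    for (rep in 1:40) {
      n <- sample(60:160, 1)
      dates <- as.Date("2021-02-14") + sort(sample(0:(n + 20), n))
      bleeding <- runif(n) < 0.18
      rec <- data.frame(athlete_id = "X", date = dates, bleeding = bleeding)
      onsets <- oracle_onsets(dates, bleeding)
      cyc <- suppressWarnings(segment_cycles(rec))
      expect_equal(nrow(cyc), max(0L, length(onsets) - 1L))
      if (nrow(cyc)) {
        expect_equal(cyc$start_date, onsets[-length(onsets)])
        expect_equal(cyc$length, as.integer(diff(onsets)))
        expect_true(all(cyc$bleed_length >= 1 & cyc$bleed_length < cyc$length))
      }
    }
  })
})

test_that("a two-onset calendar yields one complete cycle", {
  dates <- as.Date("2021-02-14") + 0:39
  bleeding <- rep(FALSE, 40)
  bleeding[c(1:5, 29:33)] <- TRUE
  cyc <- segment_cycles(data.frame(athlete_id = "A", date = dates,
                                   bleeding = bleeding))
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$start_date, dates[1])
  expect_equal(cyc$length, 28L)
  expect_equal(cyc$bleed_length, 5L)
})

test_that("degenerate calendars yield no cycles", {
  dates <- as.Date("2021-02-14") + 0:89
  none <- segment_cycles(data.frame(date = dates, bleeding = FALSE))
  expect_equal(nrow(none), 0L)
  single <- segment_cycles(data.frame(date = dates,
                                      bleeding = c(rep(TRUE, 4), rep(FALSE, 86))))
  expect_equal(nrow(single), 0L)
})

test_that("ovulation prediction follows the fixed-luteal calendar rule", {
  expect_equal(predict_ovulation(28, 5), 14L)
  expect_equal(predict_ovulation(35, 5), 21L)
  expect_equal(predict_ovulation(21, 5), 7L)
  expect_equal(predict_ovulation(21, 6), 7L)
  # clamp keeps ovulation after menses
  expect_equal(predict_ovulation(21, 7), 8L)
  expect_warning(po <- predict_ovulation(18, 4), "proportional")
  expect_true(po >= 5 && po <= 17)
})

test_that("the 28-day cycle hits the nominal sampling-day anchors", {
  ph <- function(d) as.character(classify_mc_phase(d, 28, 5))
  expect_identical(ph(3), "menses")
  expect_identical(ph(8), "mid_follicular")
  expect_identical(ph(14), "late_follicular")
  expect_identical(ph(16), "early_luteal")
  expect_identical(ph(24), "mid_luteal")
  expect_identical(ph(28), "premenstrual")
})

test_that("the six phases partition every cycle exactly", {
  for (L in c(21:36, 45)) {
    for (b in c(2, 5, 7)) {
      ph <- classify_mc_phase(seq_len(L), L, b)
      expect_false(anyNA(ph))
      expect_equal(sum(table(ph)), L)
      # menses occupies exactly the bleeding window
      expect_equal(which(ph == "menses"), seq_len(b))
      # premenstrual is the last days of the cycle
      expect_true(all(which(ph == "premenstrual") > L - 5))
    }
  }
  # short cycles scale proportionally instead of failing
  suppressWarnings(ph <- classify_mc_phase(1:18, 18, 3))
  expect_false(anyNA(ph))
  expect_equal(sum(table(ph)), 18L)
  expect_error(classify_mc_phase(29, 28, 5), "out of range")
})

test_that("pill regimens classify into pause and active phases", {
  expect_identical(as.character(classify_hc_phase(3, "monophasic")), "pause")
  expect_identical(as.character(classify_hc_phase(3, "triphasic")), "pause")
  expect_identical(as.character(classify_hc_phase(12, "monophasic")), "phase1")
  # monophasic packs have a single active phase
  expect_true(all(classify_hc_phase(8:28, "monophasic") == "phase1"))
  expect_identical(as.character(classify_hc_phase(25, "biphasic")), "phase2")
  expect_identical(as.character(classify_hc_phase(17, "biphasic")), "phase1")
  expect_error(classify_hc_phase(29, "biphasic"), "out of range")
})

test_that("the binary scheme is exactly the bleeding flag", {
  with_seed(11, {
    bleeding <- runif(200) < 0.2
    ph <- classify_binary(bleeding)
    expect_equal(sum(ph == "menses"), sum(bleeding))
    expect_equal(which(ph == "menses"), which(bleeding))
  })
})

test_that("phase assignment covers complete cycles only and anchors HC packs", {
  co <- generate_cohort(quick_config(seed = 7L))
  mc <- assign_phases(co$daily, co$profiles, "mc6")
  expect_true(all(mc$athlete_id %in%
                    co$profiles$athlete_id[co$profiles$group == "natural_mc"]))
  expect_false(anyNA(mc$phase))
  # every labelled day's phase matches a fresh classification of its cycle day
  one <- co$daily[co$daily$athlete_id == "MC01", ]
  cyc <- segment_cycles(one)
  lab <- mc[mc$athlete_id == "MC01", ]
  expect_true(all(lab$cycle_index %in% cyc$cycle_index))
  expect_true(all(lab$date >= min(cyc$start_date)))
  expect_lt(max(lab$date), max(cyc$start_date) + cyc$length[nrow(cyc)])

  hc <- assign_phases(co$daily, co$profiles, "hc")
  expect_true(all(hc$phase[!is.na(hc$phase)] %in% hc_phases()))
  # bleeding days must sit inside the inferred pause
  m <- merge(co$daily, hc[c("athlete_id", "date", "phase")])
  expect_true(all(m$phase[m$bleeding] == "pause"))

  bin <- assign_phases(co$daily, co$profiles, "binary")
  expect_equal(nrow(bin), sum(!is.na(co$daily$bleeding)))
})

test_that("hormone ordering checks pass, fail and go indeterminate as expected", {
  s <- data.frame(phase = c("mid_follicular", "late_follicular", "mid_luteal"),
                  estradiol_mean = c(2.5, 6.9, 6.0),
                  estradiol_sd = c(1.5, 4.2, 3.8),
                  progesterone_mean = c(38.1, 42.8, 81.85),
                  progesterone_sd = c(31.3, 56.9, 35.7), n = c(20, 20, 20))
  chk <- check_hormone_ordering(s)
  expect_true(chk$all_pass)
  expect_true(all(chk$checks == "pass"))

  tie <- s
  tie$estradiol_mean <- c(2.5, 6.0, 6.0)  # tie is not strictly highest
  expect_identical(unname(check_hormone_ordering(tie)$checks["estradiol_peak_late_follicular"]),
                   "fail")

  part <- check_hormone_ordering(s[3, ])
  expect_true(all(part$checks == "indeterminate"))
})
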