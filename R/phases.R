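# Cycle segmentation and phase classification.
#
# Natural cycles are split into six calendar phases anchored on a predicted
# ovulation day (fixed-luteal calendar rule, default 14 days); combined-pill
# regimens into a withdrawal "pause" plus one or two active phases; and the
# whole cohort can be labelled by a binary bleeding-based menses scheme.

#' Phase level sets
#'
#' Phase labels for the three classification schemes: the six-phase natural
#' menstrual cycle (`mc6`), the 2-3-phase pill regimen (`hc`), and the
#' binary bleeding-based split (`binary`).
#'
#' @return Character vector of phase levels, in cycle order.
#' @export
mc_phases <- function() {
  c("menses", "mid_follicular", "late_follicular", "early_luteal",
    "mid_luteal", "premenstrual")
}

#' @rdname mc_phases
#' @export
hc_phases <- function() c("pause", "phase1", "phase2")

#' @rdname mc_phases
#' @export
binary_phases <- function() c("menses", "no_menses")

#' Phase-window configuration for the six-phase scheme
#'
#' Window lengths (days) used by [classify_mc_phase()]. `luteal_days` is the
#' assumed fixed luteal length behind the calendar ovulation prediction;
#' `late_follicular`, `early_luteal` and `premenstrual` are the widths of
#' the corresponding windows. For cycles shorter than 21 days the windows
#' are rescaled proportionally to `length / reference_length`.
#'
#' @param luteal_days Assumed luteal length (default 14).
#' @param late_follicular Width of the window ending at predicted ovulation.
#' @param early_luteal Width of the window starting after predicted ovulation.
#' @param premenstrual Width of the cycle-final window.
#' @param reference_length Reference cycle length for proportional scaling.
#' @return A list of class `phase_windows`.
#' @export
phase_windows <- function(luteal_days = 14, late_follicular = 4,
                          early_luteal = 4, premenstrual = 4,
                          reference_length = 28) {
  stopifnot(luteal_days >= 1, late_follicular >= 1, early_luteal >= 0,
            premenstrual >= 0, reference_length >= 21)
  structure(list(luteal_days = luteal_days, late_follicular = late_follicular,
                 early_luteal = early_luteal, premenstrual = premenstrual,
                 reference_length = reference_length),
            class = "phase_windows")
}

#' Predict the calendar ovulation day of a cycle
#'
#' Fixed-luteal calendar rule: predicted ovulation falls `luteal_days`
#' (default 14) before the end of the cycle, clamped to at least one day
#' after the end of menses. Cycles shorter than 21 days trigger a warning
#' and fall back to proportional scaling of the rule.
#'
#' @param length Cycle length in days.
#' @param bleed_length Length of menses in days.
#' @param windows A [phase_windows()] configuration.
#' @return Predicted ovulation as a 1-based cycle day.
#' @export
predict_ovulation <- function(length, bleed_length, windows = phase_windows()) {
  stopifnot(length >= 2, bleed_length >= 1, bleed_length < length)
  if (length < 21) {
    warning(sprintf("cycle length %d < 21 days: using proportional phase scaling",
                    length), call. = FALSE)
    po <- round(length * (windows$reference_length - windows$luteal_days) /
                  windows$reference_length)
  } else {
    po <- length - windows$luteal_days
  }
  as.integer(min(max(po, bleed_length + 1), length - 1))
}

.scaled_windows <- function(windows, length) {
  if (length >= 21) return(windows)
  f <- length / windows$reference_length
  windows$late_follicular <- max(1, round(windows$late_follicular * f))
  windows$early_luteal <- max(1, round(windows$early_luteal * f))
  windows$premenstrual <- max(1, round(windows$premenstrual * f))
  windows
}

#' Classify cycle days under the six-phase natural-cycle scheme
#'
#' Assigns each 1-based cycle day exactly one of the six phases: menses
#' (days 1..bleed_length), then, by boundary precedence
#' menses > premenstrual > late_follicular > early_luteal > mid_follicular >
#' mid_luteal: premenstrual covers the final `premenstrual` days of the
#' cycle, late_follicular the `late_follicular` days ending at predicted
#' ovulation, early_luteal the `early_luteal` days after it, mid_follicular
#' the remaining pre-ovulatory days and mid_luteal the remainder. For a
#' 28-day cycle with 5 bleeding days this puts day 8 in mid_follicular,
#' day 14 in late_follicular and day 24 in mid_luteal, matching the nominal
#' hormone-sampling anchors.
#'
#' @param day Vector of 1-based cycle days.
#' @param length Cycle length in days.
#' @param bleed_length Menses length in days.
#' @param predicted_ovulation Optional ovulation day; computed by
#'   [predict_ovulation()] when `NULL`.
#' @param windows A [phase_windows()] configuration.
#' @return Factor of phases with levels [mc_phases()].
#' @export
classify_mc_phase <- function(day, length, bleed_length,
                              predicted_ovulation = NULL,
                              windows = phase_windows()) {
  if (any(day < 1 | day > length)) {
    stop(sprintf("cycle day out of range 1..%d", length))
  }
  po <- predicted_ovulation %||% predict_ovulation(length, bleed_length, windows)
  w <- .scaled_windows(windows, length)
  p <- rep(NA_character_, length(day))
  assign_if <- function(cond, lab) p[is.na(p) & cond] <<- lab
  assign_if(day <= bleed_length, "menses")
  assign_if(day > length - w$premenstrual, "premenstrual")
  assign_if(day >= po - w$late_follicular + 1 & day <= po, "late_follicular")
  assign_if(day > po & day <= po + w$early_luteal, "early_luteal")
  assign_if(day <= po, "mid_follicular")
  p[is.na(p)] <- "mid_luteal"
  factor(p, levels = mc_phases())
}

#' Classify regimen days for a combined-pill user
#'
#' Regimen days are 1-based with day 1 the first pill-withdrawal (pause)
#' day. Days `1..pause_days` are `pause`; for a monophasic pill all active
#' days are `phase1`; for biphasic/triphasic pills the active days are split
#' into `phase1` then `phase2` at the dose-change boundary (default: after
#' active day `split_after`, used when the pack's true block boundaries are
#' unknown).
#'
#' @param day Vector of 1-based regimen days (`1..active_days + pause_days`).
#' @param pill_type `"monophasic"`, `"biphasic"` or `"triphasic"`.
#' @param active_days Pill-taking days per pack (default 21).
#' @param pause_days Withdrawal days per pack (default 7).
#' @param split_after Active day after which phase2 starts (multiphasic pills).
#' @return Factor of phases with levels [hc_phases()].
#' @export
classify_hc_phase <- function(day, pill_type, active_days = 21, pause_days = 7,
                              split_after = 10) {
  pill_type <- match.arg(pill_type, c("monophasic", "biphasic", "triphasic"))
  if (any(day < 1 | day > active_days + pause_days)) {
    stop(sprintf("regimen day out of range 1..%d", active_days + pause_days))
  }
  active_day <- day - pause_days
  p <- ifelse(day <= pause_days, "pause",
              ifelse(pill_type == "monophasic" | active_day <= split_after,
                     "phase1", "phase2"))
  factor(p, levels = hc_phases())
}

#' Classify days by menstrual status
#'
#' Binary scheme shared by the whole cohort: a day is `menses` exactly when
#' clinical bleeding was declared, regardless of contraception (withdrawal
#' bleeding counts as menses).
#'
#' @param bleeding Logical vector.
#' @return Factor with levels [binary_phases()]; `NA` stays `NA`.
#' @export
classify_binary <- function(bleeding) {
  factor(ifelse(bleeding, "menses", "no_menses"), levels = binary_phases())
}

.empty_cycles <- function() {
  data.frame(athlete_id = character(), cycle_index = integer(),
             start_date = as.Date(character()), length = integer(),
             bleed_length = integer(), predicted_ovulation = integer(),
             stringsAsFactors = FALSE)
}

#' Segment one athlete's bleeding calendar into cycles
#'
#' A cycle onset is a bleeding day preceded by at least `min_clear_days`
#' (default 14) bleed-free days, which keeps a one-day gap inside a
#' multi-day menses from splitting a cycle. A complete cycle spans one onset
#' to the day before the next; trailing days after the last onset form no
#' cycle, and a calendar with fewer than two onsets yields no cycles.
#' `bleed_length` counts from the onset through the last bleeding day
#' observed within the first `max_menses_span` days of the cycle.
#'
#' @param records One athlete's daily records (columns `date`, `bleeding`).
#' @param min_clear_days Bleed-free days required before a new onset.
#' @param max_menses_span Window (days) in which bleeding counts as menses.
#' @param windows A [phase_windows()] configuration (for ovulation prediction).
#' @return A data.frame of cycles: `athlete_id`, `cycle_index`,
#'   `start_date`, `length`, `bleed_length`, `predicted_ovulation`.
#' @export
segment_cycles <- function(records, min_clear_days = 14, max_menses_span = 10,
                           windows = phase_windows()) {
  stopifnot(all(c("date", "bleeding") %in% names(records)))
  if (anyDuplicated(records$date)) stop("duplicate dates in athlete calendar")
  records <- records[order(records$date), ]
  id <- if ("athlete_id" %in% names(records) && nrow(records)) {
    records$athlete_id[1]
  } else {
    NA_character_
  }
  bdates <- records$date[which(records$bleeding)]
  if (length(bdates) < 2) return(.empty_cycles())
  is_onset <- vapply(seq_along(bdates), function(i) {
    !any(bdates >= bdates[i] - min_clear_days & bdates < bdates[i])
  }, logical(1))
  onsets <- bdates[is_onset]
  if (length(onsets) < 2) return(.empty_cycles())
  n <- length(onsets) - 1L
  out <- .empty_cycles()
  for (i in seq_len(n)) {
    start <- onsets[i]
    len <- as.integer(onsets[i + 1] - start)
    mdates <- bdates[bdates >= start & bdates < start + max_menses_span &
                       bdates < onsets[i + 1]]
    bl <- min(as.integer(max(mdates) - start) + 1L, len - 1L)
    po <- predict_ovulation(len, bl, windows)
    out <- rbind(out, data.frame(
      athlete_id = id, cycle_index = i, start_date = start, length = len,
      bleed_length = bl, predicted_ovulation = po, stringsAsFactors = FALSE))
  }
  out
}

#' Assign a phase label to every classifiable athlete-day
#'
#' Applies the requested scheme across a cohort. Under `mc6`, only
#' natural-cycle athletes' days falling inside a complete cycle are
#' labelled. Under `hc`, pill users' regimens are anchored on withdrawal
#' bleeding: regimen day 1 (the first pause day) is taken `hc_bleed_offset`
#' days before the earliest bleeding day observed on the pack grid (so a
#' missed questionnaire on one withdrawal's first day does not shift the
#' whole regimen), and the pack is tiled forward from there. Under
#' `binary`, every day with a known bleeding flag is labelled for all
#' athletes.
#'
#' @param records Daily records data.frame.
#' @param profiles Athlete roster data.frame.
#' @param scheme `"mc6"`, `"hc"` or `"binary"`.
#' @param windows A [phase_windows()] configuration.
#' @param hc_bleed_offset Days between the start of the pill pause and the
#'   onset of withdrawal bleeding (default 1).
#' @param split_after Active-day split for multiphasic pills
#'   (see [classify_hc_phase()]).
#' @return A data.frame: `athlete_id`, `date`, `cycle_index`, `cycle_day`,
#'   `scheme`, `phase` (factor with the scheme's levels).
#' @export
assign_phases <- function(records, profiles, scheme = c("mc6", "hc", "binary"),
                          windows = phase_windows(), hc_bleed_offset = 1,
                          split_after = 10) {
  scheme <- match.arg(scheme)
  empty <- data.frame(athlete_id = character(), date = as.Date(character()),
                      cycle_index = integer(), cycle_day = integer(),
                      scheme = character(), phase = character(),
                      stringsAsFactors = FALSE)
  pieces <- list()
  if (scheme == "mc6") {
    ids <- profiles$athlete_id[profiles$group == "natural_mc"]
    for (id in ids) {
      r <- records[records$athlete_id == id, ]
      cyc <- segment_cycles(r, windows = windows)
      for (i in seq_len(nrow(cyc))) {
        sel <- r$date >= cyc$start_date[i] &
          r$date < cyc$start_date[i] + cyc$length[i]
        if (!any(sel)) next
        day <- as.integer(r$date[sel] - cyc$start_date[i]) + 1L
        ph <- classify_mc_phase(day, cyc$length[i], cyc$bleed_length[i],
                                cyc$predicted_ovulation[i], windows)
        pieces[[length(pieces) + 1L]] <- data.frame(
          athlete_id = id, date = r$date[sel], cycle_index = cyc$cycle_index[i],
          cycle_day = day, scheme = scheme, phase = as.character(ph),
          stringsAsFactors = FALSE)
      }
    }
    levels <- mc_phases()
  } else if (scheme == "hc") {
    hc <- profiles[profiles$group == "hc_user", ]
    for (j in seq_len(nrow(hc))) {
      id <- hc$athlete_id[j]
      r <- records[records$athlete_id == id, ]
      bdates <- r$date[which(r$bleeding)]
      if (!length(bdates)) next
      pack <- hc$active_days[j] + hc$pause_days[j]
      is_onset <- vapply(seq_along(bdates), function(i) {
        !any(bdates >= bdates[i] - 14 & bdates < bdates[i])
      }, logical(1))
      first <- min(bdates[is_onset])
      # earliest bleeding day observed in any pack, relative to the first
      # onset's pack grid (days just "before" it wrap to large residues)
      rel <- as.integer(bdates - first) %% pack
      rel[rel > pack - hc$pause_days[j]] <- rel[rel > pack - hc$pause_days[j]] - pack
      anchor <- first + min(rel) - hc_bleed_offset
      sel <- r$date >= anchor
      if (!any(sel)) next
      off <- as.integer(r$date[sel] - anchor)
      day <- off %% pack + 1L
      ph <- classify_hc_phase(day, hc$pill_type[j], hc$active_days[j],
                              hc$pause_days[j], split_after)
      pieces[[length(pieces) + 1L]] <- data.frame(
        athlete_id = id, date = r$date[sel], cycle_index = off %/% pack + 1L,
        cycle_day = day, scheme = scheme, phase = as.character(ph),
        stringsAsFactors = FALSE)
    }
    levels <- hc_phases()
  } else {
    sel <- !is.na(records$bleeding)
    pieces[[1L]] <- data.frame(
      athlete_id = records$athlete_id[sel], date = records$date[sel],
      cycle_index = NA_integer_, cycle_day = NA_integer_, scheme = scheme,
      phase = as.character(classify_binary(records$bleeding[sel])),
      stringsAsFactors = FALSE)
    levels <- binary_phases()
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else empty
  out$phase <- factor(out$phase, levels = levels)
  out
}

#' Summarise hormone samples by phase
#'
#' Maps each sample's nominal day to its target phase (natural cycle:
#' 8 = mid_follicular, 14 = late_follicular, 24 = mid_luteal; pill users:
#' 8 and 14 fall in phase1, 24 in phase2 of the regimen) and reports the
#' mean and SD of estradiol and progesterone per phase.
#'
#' @param samples Hormone sample data.frame (see [read_hormones_csv()]).
#' @param profiles Optional roster; when given, only athletes in `group`
#'   are summarised.
#' @param group `"natural_mc"` or `"hc_user"`.
#' @return A data.frame: `phase`, `estradiol_mean`, `estradiol_sd`,
#'   `progesterone_mean`, `progesterone_sd`, `n`.
#' @export
hormone_phase_summary <- function(samples, profiles = NULL, group = "natural_mc") {
  if (!is.null(profiles)) {
    keep <- profiles$athlete_id[profiles$group == group]
    samples <- samples[samples$athlete_id %in% keep, ]
  }
  map <- if (group == "natural_mc") {
    c("8" = "mid_follicular", "14" = "late_follicular", "24" = "mid_luteal")
  } else {
    c("8" = "phase1", "14" = "phase1", "24" = "phase2")
  }
  phase <- unname(map[as.character(samples$nominal_day)])
  out <- do.call(rbind, lapply(unique(map), function(ph) {
    sel <- which(phase == ph)
    if (!length(sel)) return(NULL)
    data.frame(phase = ph,
               estradiol_mean = mean(samples$estradiol[sel]),
               estradiol_sd = sd(samples$estradiol[sel]),
               progesterone_mean = mean(samples$progesterone[sel]),
               progesterone_sd = sd(samples$progesterone[sel]),
               n = length(sel), stringsAsFactors = FALSE)
  }))
  out %||% data.frame(phase = character(), estradiol_mean = numeric(),
                      estradiol_sd = numeric(), progesterone_mean = numeric(),
                      progesterone_sd = numeric(), n = integer())
}

#' Check hormone phase means against the expected cycle ordering
#'
#' Three checks on a natural-cycle [hormone_phase_summary()]: progesterone
#' strictly highest in the mid-luteal phase, estradiol strictly highest in
#' the late-follicular phase, and both hormones strictly lowest in the
#' mid-follicular phase. A check involving a missing phase is marked
#' `indeterminate`; ties fail (not strictly highest/lowest).
#'
#' @param summary Output of [hormone_phase_summary()] for a natural-cycle group.
#' @return An object of class `hormone_ordering`: a list with `checks`
#'   (named character vector `pass`/`fail`/`indeterminate`) and `all_pass`.
#' @export
check_hormone_ordering <- function(summary) {
  get_val <- function(ph, col) {
    i <- match(ph, summary$phase)
    if (is.na(i)) NA_real_ else summary[[col]][i]
  }
  e2 <- vapply(c("mid_follicular", "late_follicular", "mid_luteal"),
               get_val, numeric(1), col = "estradiol_mean")
  p4 <- vapply(c("mid_follicular", "late_follicular", "mid_luteal"),
               get_val, numeric(1), col = "progesterone_mean")
  verdict <- function(cond, needed) {
    if (anyNA(needed)) "indeterminate" else if (cond) "pass" else "fail"
  }
  checks <- c(
    progesterone_peak_mid_luteal =
      verdict(isTRUE(p4[3] > max(p4[1:2])), p4),
    estradiol_peak_late_follicular =
      verdict(isTRUE(e2[2] > max(e2[c(1, 3)])), e2),
    nadir_mid_follicular =
      verdict(isTRUE(e2[1] < min(e2[2:3]) && p4[1] < min(p4[2:3])), c(e2, p4))
  )
  structure(list(checks = checks, all_pass = all(checks == "pass")),
            class = "hormone_ordering")
}

#' @export
print.hormone_ordering <- function(x, ...) {
  cat("Hormone-by-phase ordering checks:\n")
  for (nm in names(x$checks)) cat(sprintf("  %-32s %s\n", nm, x$checks[nm]))
  invisible(x)
}
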