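# Domain types and CSV interchange for longitudinal monitoring data.
#
# All collections are plain data.frames:
#   daily records  -- one row per athlete-day (see daily_columns())
#   roster         -- one row per athlete (athlete_id, group, pill_type,
#                     active_days, pause_days)
#   hormones       -- one row per salivary sample
#
# Missing values are NA internally and empty cells on disk. Dates are
# ISO-8601. Bedtime is stored as minutes after 12:00 noon so that late-night
# values stay monotone (22:00 = 600 < 01:00 = 780); sleep duration is hours.

#' Column names of a daily monitoring record table
#'
#' @return Character vector of the canonical `daily.csv` columns, in order.
#' @export
daily_columns <- function() {
  c("athlete_id", "date", "bleeding", "sleep_quality", "fitness", "mood",
    "self_performance", "rpe", "sleep_duration", "bedtime", "symptoms",
    "pain_intensity", "coach_performance")
}

#' Seed list of symptom labels
#'
#' The symptom vocabulary is open (any free string can appear in the
#' `symptoms` column); this list only seeds the synthetic generator and
#' documentation with labels typical of menstrual-symptom monitoring.
#'
#' @return Character vector of symptom labels.
#' @export
canonical_symptoms <- function() {
  c("digestive troubles", "cramps", "headaches", "fatigue", "back pain",
    "bloating", "breast tenderness", "mood swings", "acne", "insomnia")
}

.blank <- function(x) is.na(x) | !nzchar(trimws(x))

.fail_cell <- function(file, row, field, msg) {
  stop(sprintf("%s row %d, field '%s': %s", file, row, field, msg),
       call. = FALSE)
}

.parse_numeric_col <- function(x, field, file) {
  out <- rep(NA_real_, length(x))
  idx <- which(!.blank(x))
  if (!length(idx)) return(out)
  v <- suppressWarnings(as.numeric(x[idx]))
  if (anyNA(v)) {
    bad <- idx[which(is.na(v))[1]]
    .fail_cell(file, bad, field, sprintf("malformed value '%s'", x[bad]))
  }
  out[idx] <- v
  out
}

.check_range <- function(v, lo, hi, field, file, integer = TRUE) {
  bad <- which(!is.na(v) &
                 (v < lo | v > hi | (integer & v != round(v))))
  if (length(bad)) {
    .fail_cell(file, bad[1], field,
               sprintf("value %s outside %s..%s%s", format(v[bad[1]]), lo, hi,
                       if (integer) " (integer scale)" else ""))
  }
  if (integer) as.integer(v) else v
}

.parse_date_col <- function(x, field, file) {
  if (any(.blank(x))) .fail_cell(file, which(.blank(x))[1], field, "missing date")
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    .fail_cell(file, bad, field, sprintf("malformed date '%s'", x[bad]))
  }
  d
}

.parse_bool_col <- function(x, field, file) {
  out <- rep(NA, length(x))
  idx <- which(!.blank(x))
  v <- trimws(tolower(x[idx]))
  ok <- v %in% c("0", "1", "true", "false")
  if (!all(ok)) {
    bad <- idx[which(!ok)[1]]
    .fail_cell(file, bad, field, sprintf("malformed boolean '%s'", x[bad]))
  }
  out[idx] <- v %in% c("1", "true")
  out
}

# "HH:MM" -> hours; plain numbers pass through.
.parse_duration_col <- function(x, field, file) {
  idx <- which(!.blank(x) & grepl(":", x, fixed = TRUE))
  x2 <- x
  for (i in idx) {
    p <- suppressWarnings(as.integer(strsplit(trimws(x[i]), ":", fixed = TRUE)[[1]]))
    if (length(p) != 2 || anyNA(p) || p[2] < 0 || p[2] > 59) {
      .fail_cell(file, i, field, sprintf("malformed time '%s'", x[i]))
    }
    x2[i] <- format(p[1] + p[2] / 60)
  }
  .parse_numeric_col(x2, field, file)
}

# "HH:MM" clock time -> minutes after noon (times before 12:00 are treated
# as after midnight); plain numbers pass through unchanged.
.parse_bedtime_col <- function(x, field, file) {
  idx <- which(!.blank(x) & grepl(":", x, fixed = TRUE))
  x2 <- x
  for (i in idx) {
    p <- suppressWarnings(as.integer(strsplit(trimws(x[i]), ":", fixed = TRUE)[[1]]))
    if (length(p) != 2 || anyNA(p) || p[1] < 0 || p[1] > 23 || p[2] < 0 || p[2] > 59) {
      .fail_cell(file, i, field, sprintf("malformed time '%s'", x[i]))
    }
    h <- if (p[1] < 12) p[1] + 24 else p[1]
    x2[i] <- format((h - 12) * 60 + p[2])
  }
  .parse_numeric_col(x2, field, file)
}

# Canonical symptom cell: trimmed, de-duplicated, sorted, ';'-joined.
.canon_symptoms <- function(x) {
  x[is.na(x)] <- ""
  vapply(strsplit(x, ";", fixed = TRUE), function(t) {
    t <- unique(trimws(t))
    paste(sort(t[nzchar(t)]), collapse = ";")
  }, character(1))
}

#' Read a daily monitoring CSV
#'
#' Reads one row per athlete-day. Empty cells map to `NA`; the `symptoms`
#' cell is a `;`-separated set of free-text labels (canonicalised to a
#' sorted, de-duplicated string). `sleep_duration` accepts hours or
#' `"HH:MM"`; `bedtime` accepts minutes-after-noon or a `"HH:MM"` clock time
#' (clock times before 12:00 are read as after midnight). Likert fields are
#' validated against their 1-10 (or 0-10) ranges; a malformed or
#' out-of-range cell raises an error naming the row and field.
#'
#' @param path Path to a CSV file with the columns of [daily_columns()].
#' @return A data.frame of daily records.
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  miss <- setdiff(daily_columns(), names(raw))
  if (length(miss)) stop("daily csv is missing columns: ", paste(miss, collapse = ", "))
  f <- basename(path)
  out <- data.frame(
    athlete_id = trimws(raw$athlete_id),
    date = .parse_date_col(raw$date, "date", f),
    bleeding = .parse_bool_col(raw$bleeding, "bleeding", f),
    stringsAsFactors = FALSE
  )
  if (any(.blank(out$athlete_id))) {
    .fail_cell(f, which(.blank(out$athlete_id))[1], "athlete_id", "missing athlete id")
  }
  for (v in c("sleep_quality", "fitness", "mood", "self_performance")) {
    out[[v]] <- .check_range(.parse_numeric_col(raw[[v]], v, f), 1, 10, v, f)
  }
  out$rpe <- .check_range(.parse_numeric_col(raw$rpe, "rpe", f), 0, 10, "rpe", f,
                          integer = FALSE)
  out$sleep_duration <- .parse_duration_col(raw$sleep_duration, "sleep_duration", f)
  if (any(out$sleep_duration < 0, na.rm = TRUE)) {
    .fail_cell(f, which(out$sleep_duration < 0)[1], "sleep_duration", "negative duration")
  }
  out$bedtime <- .parse_bedtime_col(raw$bedtime, "bedtime", f)
  out$symptoms <- .canon_symptoms(raw$symptoms)
  out$pain_intensity <- .check_range(
    .parse_numeric_col(raw$pain_intensity, "pain_intensity", f),
    0, 10, "pain_intensity", f)
  out$coach_performance <- .check_range(
    .parse_numeric_col(raw$coach_performance, "coach_performance", f),
    1, 10, "coach_performance", f)
  out[daily_columns()]
}

#' Write a daily monitoring CSV
#'
#' Inverse of [read_daily_csv()]: `read_daily_csv(write_daily_csv(x))`
#' reproduces `x` field-for-field.
#'
#' @param records Data.frame of daily records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(records, path) {
  out <- records[daily_columns()]
  out$date <- format(out$date, "%Y-%m-%d")
  out$bleeding <- ifelse(is.na(out$bleeding), NA, as.integer(out$bleeding))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an athlete roster CSV
#'
#' Columns: `athlete_id, group, pill_type, active_days, pause_days`.
#' `group` is `natural_mc` or `hc_user`; a natural-cycle athlete must have
#' `pill_type = none` and vice versa. Pill users default to a 21-day active /
#' 7-day pause regimen when the counts are left blank.
#'
#' @param path Path to the roster CSV.
#' @return A data.frame of athlete profiles.
#' @export
read_athletes_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  need <- c("athlete_id", "group", "pill_type", "active_days", "pause_days")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("athletes csv is missing columns: ", paste(miss, collapse = ", "))
  f <- basename(path)
  grp <- trimws(raw$group)
  bad <- which(!grp %in% c("natural_mc", "hc_user"))
  if (length(bad)) .fail_cell(f, bad[1], "group", sprintf("unknown group '%s'", grp[bad[1]]))
  pill <- trimws(raw$pill_type)
  pill[.blank(pill)] <- "none"
  bad <- which(!pill %in% c("none", "monophasic", "biphasic", "triphasic"))
  if (length(bad)) .fail_cell(f, bad[1], "pill_type", sprintf("unknown pill type '%s'", pill[bad[1]]))
  bad <- which((grp == "natural_mc") != (pill == "none"))
  if (length(bad)) {
    .fail_cell(f, bad[1], "pill_type",
               "group 'natural_mc' requires pill_type 'none' and 'hc_user' a pill type")
  }
  act <- .parse_numeric_col(raw$active_days, "active_days", f)
  pau <- .parse_numeric_col(raw$pause_days, "pause_days", f)
  act[is.na(act) & grp == "hc_user"] <- 21
  pau[is.na(pau) & grp == "hc_user"] <- 7
  act[grp == "natural_mc"] <- NA
  pau[grp == "natural_mc"] <- NA
  bad <- which(grp == "hc_user" & (act < 1 | pau < 0))
  if (length(bad)) .fail_cell(f, bad[1], "active_days", "need active_days >= 1 and pause_days >= 0")
  data.frame(athlete_id = trimws(raw$athlete_id), group = grp, pill_type = pill,
             active_days = as.integer(act), pause_days = as.integer(pau),
             stringsAsFactors = FALSE)
}

#' @rdname read_athletes_csv
#' @param profiles Data.frame of athlete profiles.
#' @export
write_athletes_csv <- function(profiles, path) {
  utils::write.csv(
    profiles[c("athlete_id", "group", "pill_type", "active_days", "pause_days")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a salivary hormone sample CSV
#'
#' Columns: `athlete_id, date, cycle_day, nominal_day, estradiol,
#' progesterone`. Samples target nominal cycle days 8, 14 and 24 with a
#' tolerance of two days (`|cycle_day - nominal_day| <= 2`); concentrations
#' are pg/mL and must be positive.
#'
#' @param path Path to the hormone CSV.
#' @return A data.frame of hormone samples.
#' @export
read_hormones_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  need <- c("athlete_id", "date", "cycle_day", "nominal_day", "estradiol", "progesterone")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("hormones csv is missing columns: ", paste(miss, collapse = ", "))
  f <- basename(path)
  out <- data.frame(
    athlete_id = trimws(raw$athlete_id),
    date = .parse_date_col(raw$date, "date", f),
    cycle_day = .check_range(.parse_numeric_col(raw$cycle_day, "cycle_day", f),
                             1, 365, "cycle_day", f),
    nominal_day = .check_range(.parse_numeric_col(raw$nominal_day, "nominal_day", f),
                               1, 365, "nominal_day", f),
    estradiol = .parse_numeric_col(raw$estradiol, "estradiol", f),
    progesterone = .parse_numeric_col(raw$progesterone, "progesterone", f),
    stringsAsFactors = FALSE
  )
  bad <- which(!out$nominal_day %in% c(8L, 14L, 24L))
  if (length(bad)) .fail_cell(f, bad[1], "nominal_day", "must be 8, 14 or 24")
  bad <- which(abs(out$cycle_day - out$nominal_day) > 2)
  if (length(bad)) .fail_cell(f, bad[1], "cycle_day", "outside the +/- 2 day sampling window")
  for (v in c("estradiol", "progesterone")) {
    bad <- which(is.na(out[[v]]) | out[[v]] <= 0)
    if (length(bad)) .fail_cell(f, bad[1], v, "concentration must be a positive number")
  }
  out
}

#' @rdname read_hormones_csv
#' @param samples Data.frame of hormone samples.
#' @export
write_hormones_csv <- function(samples, path) {
  out <- samples[c("athlete_id", "date", "cycle_day", "nominal_day",
                   "estradiol", "progesterone")]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Consistency report for a cohort
#'
#' Report-only validation: flags athletes who never declared bleeding
#' (amenorrhea candidates, excluded from phase analyses downstream),
#' duplicated athlete-date pairs, and records whose athlete is absent from
#' the roster. Never mutates its inputs.
#'
#' @param profiles Athlete roster data.frame.
#' @param records Daily records data.frame.
#' @return An object of class `cohort_validation` with components
#'   `amenorrheic`, `duplicates`, `unknown_athletes` and `n_issues`.
#' @export
validate_cohort <- function(profiles, records) {
  ids <- unique(records$athlete_id)
  amen <- vapply(ids, function(id) {
    !any(records$bleeding[records$athlete_id == id], na.rm = TRUE)
  }, logical(1))
  key <- paste(records$athlete_id, records$date)
  dup <- records[duplicated(key), c("athlete_id", "date")]
  unknown <- setdiff(ids, profiles$athlete_id)
  out <- list(
    amenorrheic = ids[amen],
    duplicates = dup,
    unknown_athletes = unknown,
    n_issues = nrow(dup) + length(unknown)
  )
  class(out) <- "cohort_validation"
  out
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation report\n")
  cat("  amenorrhea candidates (no bleeding declared): ",
      if (length(x$amenorrheic)) paste(x$amenorrheic, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  duplicate athlete-dates: ", nrow(x$duplicates), "\n", sep = "")
  cat("  records for unknown athletes: ",
      if (length(x$unknown_athletes)) paste(x$unknown_athletes, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
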