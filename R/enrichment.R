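# Top-quintile phase-enrichment analysis.
#
# Per athlete, each monitored 1-10 score is binarised against that
# athlete's own empirical 0.8-quantile (a day is "top" when its score
# strictly exceeds the quantile), top-day counts are normalised by phase
# exposure and athlete, and the resulting per-phase distribution is tested
# against a discrete uniform 1/k by a chi-square goodness-of-fit test.
# Pearson residuals flag the phases driving a significant test.

#' Two-sided standard-normal critical value
#'
#' `qnorm(1 - alpha / 2)`: the threshold a Pearson residual must exceed to
#' flag a phase at level `alpha` (1.96 at alpha = 0.05, 1.64 at 0.1).
#'
#' @param alpha Significance level(s).
#' @return Numeric vector of critical values.
#' @export
critical_z <- function(alpha) qnorm(1 - alpha / 2)

#' Binarise one athlete's scores at their top quintile
#'
#' The threshold is the `ceiling(prob * n)`-th order statistic of the
#' athlete's own non-missing values; a day is flagged (1) only when its
#' value strictly exceeds the threshold, so ties at the quantile are never
#' flagged and heavily tied Likert data never exceed the nominal 20%.
#'
#' @param values One athlete's scores for one variable (may contain `NA`).
#' @param prob Quantile order (default 0.8).
#' @param min_n Minimum number of non-missing values; below it the athlete
#'   is skipped with a warning and `NULL` is returned.
#' @return Integer vector of 0/1 indicators aligned with `values` (`NA`
#'   where the value is missing), or `NULL`.
#' @export
binarize_top_quintile <- function(values, prob = 0.8, min_n = 5) {
  v <- values[!is.na(values)]
  if (length(v) < min_n) {
    warning(sprintf("fewer than %d non-missing values: athlete-variable skipped",
                    min_n), call. = FALSE)
    return(NULL)
  }
  thr <- sort(v)[ceiling(prob * length(v))]
  as.integer(values > thr)
}

#' Exposure-normalised top-day counts per phase
#'
#' For each athlete and phase, the top-day rate is the number of flagged
#' days divided by the number of observed days in that phase; rates are
#' averaged over athletes (athletes with no exposure to a phase contribute
#' nothing to that phase's mean) and rescaled so the normalised counts sum
#' to the raw total of flagged days. This makes the observed vector
#' invariant to unequal phase exposure across athletes while keeping the
#' chi-square total interpretable. `normalize = FALSE` returns raw counts.
#'
#' @param indicator 0/1 top-day indicators (one per labelled athlete-day).
#' @param phase Phase factor aligned with `indicator`; its levels define
#'   the cells.
#' @param athlete Athlete id aligned with `indicator` (a single string is
#'   recycled).
#' @param normalize Use the rate-mean normalisation (default) or raw counts.
#' @return Named numeric vector of observed counts per phase level.
#' @export
normalized_phase_counts <- function(indicator, phase, athlete = "all",
                                    normalize = TRUE) {
  keep <- !is.na(indicator) & !is.na(phase)
  indicator <- indicator[keep]
  phase <- if (is.factor(phase)) phase[keep] else factor(phase[keep])
  athlete <- rep_len(athlete, length(keep))[keep]
  days <- tapply(indicator, list(athlete, phase), length)
  exposure <- colSums(days, na.rm = TRUE)
  if (any(exposure == 0)) {
    stop("no observed days in phase: ",
         paste(levels(phase)[exposure == 0], collapse = ", "))
  }
  if (!normalize) {
    tot <- tapply(indicator, phase, sum)
    tot[is.na(tot)] <- 0
    return(tot)
  }
  tops <- tapply(indicator, list(athlete, phase), sum)
  rates <- tops / days
  obs <- apply(rates, 2, mean, na.rm = TRUE)
  total_top <- sum(indicator)
  if (sum(obs) > 0) obs <- obs * total_top / sum(obs) else obs[] <- 0
  obs
}

#' Chi-square goodness of fit against a discrete uniform
#'
#' Tests observed per-phase counts against the uniform distribution with
#' parameter 1/k: expected counts are `sum(observed) / k` in every phase,
#' the statistic is `sum((O - E)^2 / E)` on `k - 1` degrees of freedom and
#' the p-value comes from the upper chi-square tail.
#'
#' @param observed Observed (possibly normalised) counts per phase.
#' @param k Number of phases (defaults to `length(observed)`).
#' @return A list: `chi2`, `df`, `p_value`, `observed`, `expected`.
#' @export
chisq_uniform_gof <- function(observed, k = length(observed)) {
  if (k < 2) stop("need at least k = 2 phases")
  total <- sum(observed)
  if (!(total > 0)) stop("total observed count must be positive")
  expected <- rep(total / k, k)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = as.integer(k - 1),
       p_value = pchisq(chi2, k - 1, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Pearson residuals and over/under-representation flags
#'
#' The residual of phase p is `(O_p - E_p) / sqrt(E_p)`. A phase is flagged
#' `over_05`/`under_05` beyond `critical_z(0.05) = 1.96` and
#' `over_10`/`under_10` beyond `critical_z(0.10) = 1.64`; residual reading
#' is gated on the omnibus chi-square being significant at `gate_alpha`
#' (pass `gate_p = NULL` to skip gating), in which case all flags are
#' `none`.
#'
#' @param observed Observed counts per phase.
#' @param expected Expected counts (default: uniform `sum/k`).
#' @param alpha Flagging levels (default `c(0.05, 0.10)`).
#' @param gate_p Omnibus chi-square p-value, or `NULL`.
#' @param gate_alpha Gate level (default 0.05).
#' @return A list: `residuals`, `flags`, `gated`, `thresholds`.
#' @export
residual_flags <- function(observed, expected = NULL, alpha = c(0.05, 0.10),
                           gate_p = NULL, gate_alpha = 0.05) {
  expected <- expected %||% rep(sum(observed) / length(observed), length(observed))
  stopifnot(length(expected) == length(observed), all(expected > 0))
  r <- (observed - expected) / sqrt(expected)
  gated <- !is.null(gate_p) && gate_p >= gate_alpha
  flags <- rep("none", length(r))
  if (!gated) {
    for (a in sort(alpha, decreasing = TRUE)) {  # looser first, stricter overrides
      z <- critical_z(a)
      lab <- sprintf("%02d", round(a * 100))
      flags[r > z] <- paste0("over_", lab)
      flags[r < -z] <- paste0("under_", lab)
    }
  }
  names(flags) <- names(r)
  list(residuals = r, flags = flags, gated = gated,
       thresholds = critical_z(sort(alpha)))
}

#' Sum declared symptoms per phase
#'
#' Raw counts (no exposure normalisation) of declared symptoms per phase
#' and symptom label; a symptom declared twice on the same day counts once.
#'
#' @param records Daily records data.frame.
#' @param phases Phase labels from [assign_phases()].
#' @return An object of class `symptom_summary`: list with `counts`
#'   (phase x symptom matrix) and `totals` (per-phase sums).
#' @export
symptom_sums <- function(records, phases) {
  m <- merge(records[c("athlete_id", "date", "symptoms")],
             phases[c("athlete_id", "date", "phase")],
             by = c("athlete_id", "date"))
  toks <- lapply(strsplit(ifelse(is.na(m$symptoms), "", m$symptoms), ";", fixed = TRUE),
                 function(t) {
                   t <- unique(trimws(t))
                   t[nzchar(t)]
                 })
  lens <- lengths(toks)
  ph_levels <- levels(m$phase) %||% sort(unique(as.character(m$phase)))
  long_phase <- factor(rep(as.character(m$phase), lens), levels = ph_levels)
  long_sym <- unlist(toks)
  counts <- if (length(long_sym)) {
    as.matrix(table(long_phase, factor(long_sym)))
  } else {
    matrix(0L, nrow = length(ph_levels), ncol = 0,
           dimnames = list(ph_levels, NULL))
  }
  names(dimnames(counts)) <- NULL
  structure(list(counts = counts, totals = rowSums(counts)),
            class = "symptom_summary")
}

#' @export
print.symptom_summary <- function(x, ...) {
  cat("Declared symptoms per phase (raw counts):\n")
  print(x$totals)
  invisible(x)
}

#' @export
as.data.frame.symptom_summary <- function(x, ...) {
  if (!ncol(x$counts)) {
    return(data.frame(phase = rownames(x$counts), symptom = NA_character_,
                      count = 0L)[0, ])
  }
  data.frame(phase = rep(rownames(x$counts), ncol(x$counts)),
             symptom = rep(colnames(x$counts), each = nrow(x$counts)),
             count = as.vector(x$counts), stringsAsFactors = FALSE)
}

#' Run the top-quintile phase-enrichment analysis
#'
#' Full pipeline for one phase scheme: assign phases, drop amenorrheic
#' athletes (no bleeding ever declared), binarise each variable per athlete
#' at the 0.8-quantile, normalise top-day counts by phase exposure and
#' athlete, test against the uniform 1/k distribution and flag phases via
#' Pearson residuals (gated on omnibus significance). Under `mc6` only
#' natural-cycle athletes enter (k = 6); under `hc` only pill users (k = 3,
#' or 2 when no athlete has a phase2); under `binary` all athletes are
#' pooled (k = 2) - the scheme used for the coach's performance evaluation.
#'
#' @param records Daily records data.frame.
#' @param profiles Athlete roster data.frame.
#' @param scheme `"mc6"`, `"hc"` or `"binary"`.
#' @param variables Score columns to analyse.
#' @param prob Quantile order for the top-score binarisation.
#' @param alpha Residual-flag levels.
#' @param gate_alpha Omnibus significance gate for residual flags.
#' @param normalize Exposure normalisation (see [normalized_phase_counts()]).
#' @param min_n Minimum non-missing days per athlete and variable.
#' @param windows,hc_bleed_offset,split_after Passed to [assign_phases()].
#' @param exclude_amenorrheic Drop athletes who never declared bleeding.
#' @return An object of class `phase_enrichment`.
#' @export
run_enrichment <- function(records, profiles, scheme = c("mc6", "hc", "binary"),
                           variables = c("sleep_quality", "fitness", "mood",
                                         "self_performance"),
                           prob = 0.8, alpha = c(0.05, 0.10), gate_alpha = 0.05,
                           normalize = TRUE, min_n = 5,
                           windows = phase_windows(), hc_bleed_offset = 1,
                           split_after = 10, exclude_amenorrheic = TRUE) {
  scheme <- match.arg(scheme)
  if (exclude_amenorrheic) {
    keep <- vapply(unique(records$athlete_id), function(id) {
      any(records$bleeding[records$athlete_id == id], na.rm = TRUE)
    }, logical(1))
    records <- records[records$athlete_id %in% names(keep)[keep], ]
  }
  grp_ids <- switch(scheme,
    mc6 = profiles$athlete_id[profiles$group == "natural_mc"],
    hc = profiles$athlete_id[profiles$group == "hc_user"],
    binary = profiles$athlete_id)
  records <- records[records$athlete_id %in% grp_ids, ]
  phases <- assign_phases(records, profiles, scheme, windows = windows,
                          hc_bleed_offset = hc_bleed_offset,
                          split_after = split_after)
  if (scheme == "hc" && !any(phases$phase == "phase2", na.rm = TRUE)) {
    phases$phase <- droplevels(phases$phase)
  }
  merged <- merge(records, phases[c("athlete_id", "date", "phase")],
                  by = c("athlete_id", "date"))
  results <- list()
  for (v in variables) {
    val <- merged[[v]]
    ind <- rep(NA_integer_, nrow(merged))
    n_ath <- 0L
    for (id in unique(merged$athlete_id)) {
      idx <- which(merged$athlete_id == id & !is.na(val))
      if (length(idx) < min_n) {
        if (length(idx)) {
          warning(sprintf("athlete %s has < %d '%s' values and is skipped",
                          id, min_n, v), call. = FALSE)
        }
        next
      }
      b <- binarize_top_quintile(val[idx], prob, min_n)
      ind[idx] <- b
      n_ath <- n_ath + 1L
    }
    keep <- !is.na(ind)
    if (!any(keep) || sum(ind[keep]) == 0) {
      warning(sprintf("variable '%s' has no top-flagged days; skipped", v),
              call. = FALSE)
      next
    }
    obs <- normalized_phase_counts(ind[keep], merged$phase[keep],
                                   merged$athlete_id[keep], normalize)
    gof <- chisq_uniform_gof(obs)
    rf <- residual_flags(obs, gof$expected, alpha, gate_p = gof$p_value,
                         gate_alpha = gate_alpha)
    results[[v]] <- list(variable = v, k = length(obs), observed = obs,
                         expected = gof$expected, chi2 = gof$chi2,
                         df = gof$df, p_value = gof$p_value,
                         residuals = rf$residuals, flags = rf$flags,
                         gated = rf$gated, n_athletes = n_ath,
                         n_days = sum(keep), total_top = sum(ind[keep]))
  }
  structure(list(scheme = scheme, results = results,
                 phase_levels = levels(merged$phase), alpha = sort(alpha),
                 gate_alpha = gate_alpha),
            class = "phase_enrichment")
}

#' @export
print.phase_enrichment <- function(x, digits = 3, ...) {
  cat(sprintf("Top-quintile phase enrichment (%s scheme, k = %d)\n",
              x$scheme, length(x$phase_levels)))
  for (res in x$results) {
    sig <- res$p_value < x$gate_alpha
    cat(sprintf("  %-17s chi2 = %6.2f, df = %d, p = %s%s\n",
                res$variable, res$chi2, res$df,
                format.pval(res$p_value, digits = digits),
                if (sig) " *" else ""))
    fl <- res$flags[res$flags != "none"]
    if (length(fl)) {
      cat(sprintf("    flags: %s\n",
                  paste(sprintf("%s (%s)", names(fl), fl), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.phase_enrichment <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(res) {
    data.frame(variable = res$variable, phase = names(res$observed),
               observed = as.numeric(res$observed),
               expected = as.numeric(res$expected),
               residual = as.numeric(res$residuals),
               flag = unname(res$flags), chi2 = res$chi2, df = res$df,
               p_value = res$p_value, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' @export
plot.phase_enrichment <- function(x, variable = NULL, ...) {
  variable <- variable %||% names(x$results)[1]
  res <- x$results[[variable]]
  if (is.null(res)) stop("no results for variable ", variable)
  bp <- barplot(res$residuals, names.arg = names(res$observed), las = 2,
                ylab = "Pearson residual", main = variable,
                ylim = range(c(res$residuals, -2.2, 2.2)) * 1.1,
                col = ifelse(res$residuals > 0, "#2c7fb8", "#d95f0e"), ...)
  abline(h = c(-1, 1) * critical_z(0.05), lty = 2)
  abline(h = c(-1, 1) * critical_z(0.10), lty = 3)
  abline(h = 0)
  invisible(bp)
}
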