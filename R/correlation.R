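# Spearman rank-correlation screen across monitored variables.

#' Number of distinct symptoms declared on a day
#'
#' Counts unique non-empty labels in each `;`-separated symptoms cell
#' (set semantics: duplicates count once). This is the symptom variable
#' entering the correlation screen.
#'
#' @param symptoms Character vector of `;`-separated symptom cells.
#' @return Integer vector of daily symptom counts.
#' @export
daily_symptom_burden <- function(symptoms) {
  symptoms[is.na(symptoms)] <- ""
  vapply(strsplit(symptoms, ";", fixed = TRUE), function(t) {
    t <- unique(trimws(t))
    sum(nzchar(t))
  }, integer(1))
}

#' Spearman correlation matrix with per-pair significance
#'
#' Pairwise-complete Spearman correlations: values are ranked with
#' average-tie correction and the correlation is the Pearson correlation
#' of the ranks. P-values use the large-sample t approximation, except
#' that cells with fewer than `exact_below` complete pairs use a seeded
#' permutation test (`n_perm` permutations). Cells with fewer than
#' `min_pairs` complete pairs, or a constant variable (zero rank
#' variance), are indeterminate (`NA`). A `symptoms` character column is
#' converted via [daily_symptom_burden()].
#'
#' @param data Data.frame of daily records (or any numeric columns).
#' @param variables Columns to correlate; defaults to the monitored set
#'   present in `data`.
#' @param alpha Significance level (default 0.05).
#' @param min_pairs Minimum complete pairs per cell (default 4).
#' @param exact_below Below this pair count the permutation p-value is used.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation test.
#' @return An object of class `spearman_screen` with matrices `rho`,
#'   `p_values`, `n_pairs` and `significant`.
#' @export
spearman_matrix <- function(data, variables = NULL, alpha = 0.05,
                            min_pairs = 4, exact_below = 30, n_perm = 10000,
                            seed = 1L) {
  default_vars <- c("self_performance", "rpe", "sleep_quality", "fitness",
                    "mood", "sleep_duration", "bedtime", "symptoms",
                    "pain_intensity", "coach_performance")
  variables <- variables %||% intersect(default_vars, names(data))
  stopifnot(length(variables) >= 2, all(variables %in% names(data)))
  X <- data[variables]
  if ("symptoms" %in% variables && is.character(X$symptoms)) {
    X$symptoms <- daily_symptom_burden(X$symptoms)
  }
  X <- as.matrix(as.data.frame(lapply(X, as.numeric)))
  p <- length(variables)
  rho <- pv <- matrix(NA_real_, p, p, dimnames = list(variables, variables))
  nn <- matrix(0L, p, p, dimnames = list(variables, variables))
  diag(rho) <- 1
  with_seed(seed, {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        cc <- which(!is.na(X[, i]) & !is.na(X[, j]))
        n <- length(cc)
        nn[i, j] <- nn[j, i] <- n
        if (n < min_pairs) next
        rx <- rank(X[cc, i])
        ry <- rank(X[cc, j])
        if (sd(rx) == 0 || sd(ry) == 0) next
        r <- cor(rx, ry)
        p_val <- if (n < exact_below) {
          perm <- replicate(n_perm, cor(rx, sample(ry)))
          (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (n_perm + 1)
        } else if (abs(r) >= 1) {
          0
        } else {
          tt <- r * sqrt((n - 2) / (1 - r^2))
          2 * pt(-abs(tt), n - 2)
        }
        rho[i, j] <- rho[j, i] <- r
        pv[i, j] <- pv[j, i] <- p_val
      }
    }
  })
  diag(nn) <- colSums(!is.na(X))
  structure(list(variables = variables, rho = rho, p_values = pv,
                 n_pairs = nn, significant = !is.na(pv) & pv < alpha,
                 alpha = alpha),
            class = "spearman_screen")
}

#' @export
print.spearman_screen <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlation screen (alpha = %g; * significant)\n",
              x$alpha))
  m <- matrix("", nrow(x$rho), ncol(x$rho), dimnames = dimnames(x$rho))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (i == j) {
        m[i, j] <- "1"
      } else if (!is.na(x$rho[i, j])) {
        m[i, j] <- paste0(format(round(x$rho[i, j], digits), nsmall = digits),
                          if (x$significant[i, j]) "*" else "")
      } else {
        m[i, j] <- "."
      }
    }
  }
  print(m, quote = FALSE, right = TRUE)
  invisible(x)
}

#' @export
as.data.frame.spearman_screen <- function(x, ...) {
  p <- length(x$variables)
  out <- NULL
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      out <- rbind(out, data.frame(
        var_a = x$variables[i], var_b = x$variables[j],
        rho = x$rho[i, j], p_value = x$p_values[i, j],
        n = x$n_pairs[i, j], significant = x$significant[i, j],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' @export
plot.spearman_screen <- function(x, ...) {
  p <- length(x$variables)
  plot(0, 0, type = "n", xlim = c(0.5, p + 0.5), ylim = c(0.5, p + 0.5),
       axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  axis(1, at = seq_len(p), labels = x$variables, las = 2, tick = FALSE,
       cex.axis = 0.7)
  axis(2, at = rev(seq_len(p)), labels = x$variables, las = 1, tick = FALSE,
       cex.axis = 0.7)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i >= j) next
      r <- x$rho[i, j]
      cx <- j
      cy <- p + 1 - i
      if (is.na(r)) next
      if (x$significant[i, j]) {
        symbols(cx, cy, circles = abs(r) / 2.2, inches = FALSE, add = TRUE,
                bg = if (r > 0) "#2c7fb8" else "#d95f0e", fg = NA)
      } else {
        points(cx, cy, pch = 4, col = "grey50")
      }
    }
  }
  invisible(x)
}
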