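#' Unit classification and inclusion filters
#'
#' Classifies units as putative interneurons (mean rate > 7 Hz AND spike
#' width < 0.3 ms; the criteria are conjunctive) or pyramidal cells, and
#' applies the inclusion filters: `active` requires at least 100 spikes
#' within run epochs; `odor_active` requires at least as many
#' odor-period spikes as there are included trials.
#'
#' @param units List of [spike_train()]s.
#' @param epochs Run epochs from [run_epochs()].
#' @param trials A [trial_table()].
#' @return A tibble with `unit_id`, `region`, `cell_type` (`NA` when the
#'   width is missing), `active`, `odor_active`, `n_run_spikes`,
#'   `n_odor_spikes`.
#' @export
classify_units <- function(units, epochs, trials) {
  inc <- included_trials(trials)
  ow <- cbind(inc$port_in, inc$port_out)
  ep <- as.matrix(epochs)
  purrr::map_dfr(units, function(u) {
    n_run <- if (nrow(ep) > 0) sum(in_windows(u$spike_times, ep)) else 0L
    n_odor <- sum(in_windows(u$spike_times, ow))
    ct <- if (is.na(u$spike_width_ms) || is.na(u$mean_rate_hz)) {
      NA_character_
    } else if (u$mean_rate_hz > 7 && u$spike_width_ms < 0.3) {
      "interneuron"
    } else {
      "pyramidal"
    }
    tibble(unit_id = u$unit_id, region = u$region, cell_type = ct,
           active = n_run >= 100, odor_active = n_odor >= nrow(inc),
           n_run_spikes = n_run, n_odor_spikes = n_odor)
  })
}

#' Task responsiveness
#'
#' Tests whether a unit changes its firing rate following odor onset. For
#' each included trial, the pre-odor window has the same duration as that
#' trial's odor-sampling period and ends at odor-port engagement; a
#' Wilcoxon signed-rank test is run on the trial-matched (post - pre) rate
#' differences for each odor identity separately (alpha 0.05 per odor,
#' uncorrected). A unit is responsive if significant for at least one
#' odor. Odors with fewer than 5 trials are skipped.
#'
#' @param unit A [spike_train()].
#' @param trials A [trial_table()].
#' @param alpha Significance level per odor.
#' @return A tibble with `unit_id`, `responsive`, and per-odor `p_odor1`,
#'   `p_odor2`, `dir_odor1`, `dir_odor2` (+1 up, -1 down, `NA` skipped).
#' @export
task_responsiveness <- function(unit, trials, alpha = 0.05) {
  inc <- included_trials(trials)
  hold <- inc$port_out - inc$port_in
  post <- count_in_windows(unit$spike_times, cbind(inc$port_in, inc$port_out)) / hold
  pre <- count_in_windows(unit$spike_times, cbind(inc$port_in - hold, inc$port_in)) / hold
  diffs <- post - pre
  one <- function(od) {
    sel <- inc$odor == od
    if (sum(sel) < 5) return(c(NA_real_, NA_real_))
    d <- diffs[sel]
    if (all(d == 0)) return(c(1, 0))
    p <- suppressWarnings(wilcox.test(d)$p.value)
    c(p, sign(median(d)))
  }
  r1 <- one(1); r2 <- one(2)
  resp <- any(c(r1[1], r2[1]) < alpha, na.rm = TRUE)
  tibble(unit_id = unit$unit_id, responsive = resp,
         p_odor1 = r1[1], p_odor2 = r2[1],
         dir_odor1 = r1[2], dir_odor2 = r2[2])
}

# Duration-weighted odor-period rates per odor label.
odor_rates <- function(spike_times, tr) {
  out <- numeric(2)
  for (od in 1:2) {
    sel <- tr$odor == od
    dur <- sum(tr$port_out[sel] - tr$port_in[sel])
    n <- sum(count_in_windows(spike_times,
                              cbind(tr$port_in[sel], tr$port_out[sel])))
    out[od] <- if (dur > 0) n / dur else NA_real_
  }
  out
}

#' Choice-selectivity index with shuffle null
#'
#' `SI = (lambda1 - lambda2) / (lambda1 + lambda2)` where `lambda1` and
#' `lambda2` are the odor-period firing rates on Odor-1 and Odor-2 correct
#' trials (duration-weighted: total spikes over total odor-period time).
#' `SI = 1` means the cell fired only on Odor-1 trials. The null
#' distribution shuffles the odor labels across correct trials; the unit
#' is selective when `|SI - null_mean| > 1.5 * null_sd`. `si_incorrect`
#' applies the same formula to incorrect trials using their odor labels,
#' so a cell following the chosen side flips sign on incorrect trials.
#'
#' @param unit A [spike_train()].
#' @param trials A [trial_table()].
#' @param n_shuffle Number of label shuffles.
#' @return A tibble of class `selectivity_result` with `unit_id`, `si`,
#'   `lambda1`, `lambda2`, `null_mean`, `null_sd`, `selective` (the 1.5 SD
#'   rule), `p_perm` (two-sided permutation p-value from the same null),
#'   `si_incorrect`, `defined`.
#' @export
choice_selectivity <- function(unit, trials, n_shuffle = 1000) {
  inc <- included_trials(trials)
  cor_tr <- inc[inc$correct, , drop = FALSE]
  if (min(table(factor(cor_tr$odor, levels = 1:2))) < 5) {
    warn("Fewer than 5 correct trials for an odor; SI is unreliable.")
  }
  lam <- odor_rates(unit$spike_times, cor_tr)
  defined <- sum(lam) > 0
  si <- if (defined) (lam[1] - lam[2]) / (lam[1] + lam[2]) else NA_real_

  null_si <- rep(NA_real_, n_shuffle)
  if (defined) {
    per_n <- count_in_windows(unit$spike_times,
                              cbind(cor_tr$port_in, cor_tr$port_out))
    per_d <- cor_tr$port_out - cor_tr$port_in
    for (s in seq_len(n_shuffle)) {
      lab <- sample(cor_tr$odor)
      n1 <- sum(per_n[lab == 1]); d1 <- sum(per_d[lab == 1])
      n2 <- sum(per_n[lab == 2]); d2 <- sum(per_d[lab == 2])
      l1 <- n1 / d1; l2 <- n2 / d2
      null_si[s] <- if (l1 + l2 > 0) (l1 - l2) / (l1 + l2) else NA_real_
    }
  }
  nm <- mean(null_si, na.rm = TRUE)
  nsd <- sd(null_si, na.rm = TRUE)
  selective <- defined && is.finite(nsd) && abs(si - nm) > 1.5 * nsd
  # two-sided permutation p alongside the 1.5 SD rule
  p_perm <- if (defined) {
    ok <- !is.na(null_si)
    (1 + sum(abs(null_si[ok] - nm) >= abs(si - nm))) / (1 + sum(ok))
  } else NA_real_

  inc_tr <- inc[!inc$correct, , drop = FALSE]
  si_inc <- NA_real_
  if (nrow(inc_tr) > 0) {
    lam_i <- odor_rates(unit$spike_times, inc_tr)
    if (isTRUE(sum(lam_i, na.rm = TRUE) > 0) && all(is.finite(lam_i))) {
      si_inc <- (lam_i[1] - lam_i[2]) / (lam_i[1] + lam_i[2])
    }
  }
  out <- tibble(unit_id = unit$unit_id, si = si, lambda1 = lam[1],
                lambda2 = lam[2], null_mean = nm, null_sd = nsd,
                selective = selective, p_perm = p_perm,
                si_incorrect = si_inc, defined = defined)
  class(out) <- c("selectivity_result", class(out))
  out
}

#' Correct- vs incorrect-trial selectivity correlation
#'
#' Spearman rank correlation between the correct-trial and incorrect-trial
#' selectivity indices across selective units. A significantly negative
#' correlation indicates that units follow the chosen side rather than the
#' presented odor.
#'
#' @param results Row-bound [choice_selectivity()] results.
#' @param selective_only Restrict to units flagged selective.
#' @return A tibble with `rho`, `p`, `n_units`.
#' @export
selectivity_correlation <- function(results, selective_only = TRUE) {
  df <- results[!is.na(results$si) & !is.na(results$si_incorrect), ]
  if (selective_only) df <- df[df$selective, ]
  if (nrow(df) < 5) abort("Need at least 5 units with defined SIs.")
  ct <- suppressWarnings(
    cor.test(df$si, df$si_incorrect, method = "spearman"))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n_units = nrow(df))
}

# Raw cross-correlogram counts of lags t_b - t_a within [-L, L), binned.
ccg_counts <- function(a, b, edges) {
  L <- max(abs(edges))
  if (length(a) == 0 || length(b) == 0) {
    return(integer(length(edges) - 1))
  }
  i1 <- findInterval(a - L, b) + 1L
  i2 <- findInterval(a + L, b)
  nper <- pmax(0L, i2 - i1 + 1L)
  tot <- sum(nper)
  if (tot == 0) return(integer(length(edges) - 1))
  ai <- rep.int(seq_along(a), nper)
  bi <- sequence(nper, from = i1[nper > 0])
  lags <- b[bi] - a[ai]
  as.integer(table(cut(lags, breaks = edges, right = FALSE)))
}

#' Jitter-corrected cross-correlogram
#'
#' Cross-correlogram between a CA1 reference train and a PFC train over
#' lags -150 to +150 ms in 2.5 ms bins, with lag = t_PFC - t_CA1 so that a
#' positive peak means CA1 leads. The null jitters each PFC spike
#' independently by uniform +/- 50 ms (preserving spike count and the
#' 50 ms-smoothed rate) and recomputes the histogram `n_jitter` times; the
#' pointwise z-score is `(raw - null_mean) / null_sd`. Global significance
#' is assessed on the maximum |z| within +/- 100 ms against the null's own
#' max-|z| distribution, which controls the family-wise false-positive
#' rate across lags at the nominal level. Significant CCGs are smoothed
#' with a Gaussian (sigma = 1 bin) for display.
#'
#' @param unitA CA1 [spike_train()] (reference).
#' @param unitB PFC [spike_train()] (jittered under the null).
#' @param windows `(start, end)` windows restricting both trains.
#' @param n_jitter Number of jitter surrogates.
#' @param jitter_s Jitter half-width (s).
#' @param alpha Significance level for the global test.
#' @return A list of class `ccg_result` with `lags_ms` (bin centers),
#'   `raw`, `z`, `smoothed`, `peak_lag_ms`, `peak_z`, `p`, `significant`.
#' @export
jitter_corrected_ccg <- function(unitA, unitB, windows = NULL,
                                 n_jitter = 1000, jitter_s = 0.05,
                                 alpha = 0.05) {
  a <- unitA$spike_times
  b <- unitB$spike_times
  if (!is.null(windows)) {
    windows <- check_windows(windows)
    a <- a[in_windows(a, windows)]
    b <- b[in_windows(b, windows)]
  }
  if (length(a) == 0 || length(b) == 0) {
    abort("Both spike trains must have at least one spike in the windows.")
  }
  edges <- seq(-0.15, 0.15, by = 0.0025)
  centers_ms <- (edges[-1] + edges[-length(edges)]) / 2 * 1000
  raw <- ccg_counts(a, b, edges)

  null_counts <- matrix(0L, n_jitter, length(raw))
  for (s in seq_len(n_jitter)) {
    bj <- sort(b + runif(length(b), -jitter_s, jitter_s))
    null_counts[s, ] <- ccg_counts(a, bj, edges)
  }
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2, sd)
  sdv[sdv == 0] <- NA_real_
  z <- (raw - mu) / sdv

  core <- abs(centers_ms) <= 100
  # global test on the pooled (observed + surrogate) ensemble: mean/sd per
  # lag over all n_jitter + 1 histograms, so the max-|z| statistics are
  # exchangeable under the null and the test is exact at its level
  pool <- rbind(raw, null_counts)
  mu_p <- colMeans(pool)
  sd_p <- apply(pool, 2, sd)
  sd_p[sd_p == 0] <- NA_real_
  zp <- sweep(sweep(pool, 2, mu_p), 2, sd_p, "/")
  max_all <- apply(abs(zp[, core, drop = FALSE]), 1, max, na.rm = TRUE)
  p <- sum(max_all >= max_all[1]) / (1 + n_jitter)
  significant <- p < alpha
  zc <- z; zc[!core] <- NA_real_
  peak_idx <- which.max(abs(zc))
  smoothed <- if (significant) gauss_smooth(raw, 1) else raw

  structure(list(lags_ms = centers_ms, raw = raw, z = z,
                 smoothed = smoothed,
                 peak_lag_ms = centers_ms[peak_idx],
                 peak_z = z[peak_idx], p = p, significant = significant,
                 n_a = length(a), n_b = length(b)),
            class = "ccg_result")
}

#' @export
print.ccg_result <- function(x, ...) {
  cat(sprintf("<ccg_result: peak z = %.2f at %.1f ms, p = %.3g%s>\n",
              x$peak_z, x$peak_lag_ms, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}
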