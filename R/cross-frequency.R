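#' Phase-amplitude coupling modulation index
#'
#' Tort-style modulation index for respiratory-rhythm phase to beta
#' amplitude coupling. RR phase is divided into 18 bins of 20 degrees, the
#' mean beta amplitude per bin is normalized to a probability vector P,
#' and MI = KL(P || uniform) / log(18), which lies in `[0, 1]`: 0 for a
#' uniform amplitude distribution, 1 when all amplitude mass falls in one
#' bin. The natural log is used; any base cancels in the ratio.
#'
#' @param phase_sig A [bandpass_zero_phase()] output for the phase-giving
#'   band (RR), or a numeric phase vector in rad.
#' @param amp_sig A [bandpass_zero_phase()] output for the
#'   amplitude-giving band (beta), or a numeric amplitude vector.
#' @param windows Optional `(start, end)` windows (s) restricting the
#'   samples (required when passing band signals; ignored for plain
#'   vectors).
#' @param n_bins Number of phase bins (18 of 20 degrees).
#' @return A tibble of class `pac_result` with `mi`, `n_samples`,
#'   `n_empty_bins`, and the normalized amplitude profile in
#'   `attr(, "profile")` (with `attr(, "edges")`).
#' @export
pac_modulation_index <- function(phase_sig, amp_sig, windows = NULL,
                                 n_bins = 18) {
  if (inherits(phase_sig, "band_signal")) {
    if (phase_sig$rate_hz != amp_sig$rate_hz) {
      abort("Phase and amplitude signals must share a rate.")
    }
    phase <- phase_sig$phase
    amp <- amp_sig$amplitude
    if (!is.null(windows)) {
      windows <- check_windows(windows)
      sel <- in_windows(band_times(phase_sig), windows)
      phase <- phase[sel]; amp <- amp[sel]
    }
  } else {
    phase <- as.numeric(phase_sig)
    amp <- as.numeric(amp_sig)
  }
  if (length(phase) != length(amp)) abort("Phase/amplitude length mismatch.")
  if (length(phase) < n_bins) abort("Too few samples for the phase bins.")

  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(wrap_pi(phase), edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  mean_amp <- rep(NA_real_, n_bins)
  agg <- tapply(amp, factor(bin, levels = seq_len(n_bins)), mean)
  mean_amp[] <- as.numeric(agg)
  empty <- which(is.na(mean_amp))
  if (length(empty) > 0) {
    # neighbor interpolation (circular) for empty bins
    filled <- mean_amp
    for (b in empty) {
      lo <- mean_amp[((b - 2) %% n_bins) + 1]
      hi <- mean_amp[(b %% n_bins) + 1]
      filled[b] <- mean(c(lo, hi), na.rm = TRUE)
    }
    mean_amp <- filled
    mean_amp[is.na(mean_amp)] <- mean(mean_amp, na.rm = TRUE)
  }
  P <- mean_amp / sum(mean_amp)
  H <- -sum(P * log(P + 1e-12))
  mi <- (log(n_bins) - H) / log(n_bins)
  out <- tibble(mi = max(0, mi), n_samples = length(phase),
                n_empty_bins = length(empty))
  attr(out, "profile") <- P
  attr(out, "edges") <- edges
  class(out) <- c("pac_result", class(out))
  out
}

#' PAC trial-shuffle null and p-value
#'
#' Permutes the trial-label assignment of the phase series against the
#' amplitude series (keeping each trial's internal phase structure
#' intact), recomputes the modulation index each time, and reports
#' `p = (1 + #null >= MI) / (1 + n_shuffle)`.
#'
#' Trials with differing sample counts are aligned by truncation to the
#' shorter trial when pairing shuffled phase with amplitude.
#'
#' @param phase_sig,amp_sig Band signals as in [pac_modulation_index()].
#' @param windows Per-trial `(start, end)` windows, one row per trial
#'   (at least 5).
#' @param n_shuffle Number of trial-label permutations.
#' @param n_bins Number of phase bins.
#' @return A `pac_result` tibble with additional columns `p`,
#'   `null_mean`, `null_sd`, and the null MIs in `attr(, "null")`.
#' @export
pac_null <- function(phase_sig, amp_sig, windows, n_shuffle = 1000,
                     n_bins = 18) {
  windows <- check_windows(windows)
  if (nrow(windows) < 2) abort("Cannot shuffle with fewer than 2 trials.")
  if (nrow(windows) < 5) warn("Fewer than 5 trials; the null is coarse.")
  if (n_shuffle < 100) warn("Fewer than 100 shuffles is unreliable.")
  t <- band_times(phase_sig)
  ph_tr <- list(); am_tr <- list()
  for (i in seq_len(nrow(windows))) {
    sel <- t >= windows[i, 1] & t < windows[i, 2]
    ph_tr[[i]] <- phase_sig$phase[sel]
    am_tr[[i]] <- amp_sig$amplitude[sel]
  }
  obs <- pac_modulation_index(unlist(ph_tr), unlist(am_tr), n_bins = n_bins)
  n_tr <- length(ph_tr)
  null_mi <- vapply(seq_len(n_shuffle), function(s) {
    perm <- sample.int(n_tr)
    ph <- list(); am <- list()
    for (i in seq_len(n_tr)) {
      m <- min(length(ph_tr[[perm[i]]]), length(am_tr[[i]]))
      if (m == 0) next
      ph[[length(ph) + 1]] <- ph_tr[[perm[i]]][seq_len(m)]
      am[[length(am) + 1]] <- am_tr[[i]][seq_len(m)]
    }
    pac_modulation_index(unlist(ph), unlist(am), n_bins = n_bins)$mi
  }, numeric(1))
  p <- (1 + sum(null_mi >= obs$mi)) / (1 + n_shuffle)
  out <- obs
  out$p <- p
  out$null_mean <- mean(null_mi)
  out$null_sd <- sd(null_mi)
  attr(out, "null") <- null_mi
  out
}

#' Session-level RR-to-beta PAC
#'
#' Convenience wrapper: filters one region's LFP in the RR and beta bands
#' and runs [pac_null()] over the included odor-sampling windows.
#'
#' @param session A `session_record`.
#' @param region Region label.
#' @param rr_band,beta_band Band edges (Hz).
#' @param n_shuffle Number of trial shuffles.
#' @return A `pac_result` tibble (see [pac_null()]).
#' @export
session_pac <- function(session, region = "CA1", rr_band = c(7, 8),
                        beta_band = c(20, 30), n_shuffle = 1000) {
  sig <- purrr::detect(session$lfp, ~ .x$region == region)
  if (is.null(sig)) abort(sprintf("No LFP channel for region %s.", region))
  ph <- bandpass_zero_phase(sig, rr_band)
  am <- bandpass_zero_phase(sig, beta_band)
  pac_null(ph, am, odor_windows(session$trials), n_shuffle = n_shuffle)
}
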