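#' Band filtering and analytic signal
#'
#' Band-pass filters an LFP trace with a 4th-order Butterworth filter
#' applied forward and backward (net zero phase) and derives the analytic
#' signal via the Hilbert transform. Phase 0 corresponds to the peak of the
#' oscillation. For very narrow bands relative to the sampling rate (where
#' a direct high-rate IIR design is ill-conditioned, e.g. 7-8 Hz at 1500
#' Hz) the trace is internally low-pass decimated before filtering and the
#' filtered signal, envelope, and unwrapped phase are interpolated back to
#' the original sample times.
#'
#' @param sig An [lfp_signal()], or a numeric vector (then `rate_hz` must
#'   be given).
#' @param band Length-2 numeric, band edges in Hz.
#' @param rate_hz Sampling rate when `sig` is a plain vector.
#' @return An object of class `band_signal` with fields `band`, `filtered`,
#'   `amplitude`, `phase` (rad in `[-pi, pi)`), `envelope`, `rate_hz`,
#'   `t0`.
#' @export
bandpass_zero_phase <- function(sig, band, rate_hz = NULL) {
  if (inherits(sig, "lfp_signal")) {
    x <- sig$samples; fs <- sig$rate_hz; t0 <- sig$t0
  } else {
    if (is.null(rate_hz)) abort("`rate_hz` is required for a plain vector.")
    x <- as.numeric(sig); fs <- rate_hz; t0 <- 0
  }
  if (band[2] >= fs / 2) {
    abort(sprintf("Band upper edge %g Hz is at/above Nyquist (%g Hz).",
                  band[2], fs / 2))
  }
  if (band[1] <= 0 || band[1] >= band[2]) abort("Need 0 < lo < hi.")

  # decimate when the band sits too low relative to Nyquist for a stable
  # high-rate IIR design
  q <- max(1L, floor(fs / (20 * band[2])))
  if (q > 1L) {
    xd <- decimate_fft(x, q)
    fsd <- fs / q
  } else {
    xd <- x; fsd <- fs
  }
  bf <- signal::butter(4, band / (fsd / 2), type = "pass")
  fd <- signal::filtfilt(bf, xd)
  a <- analytic_signal(fd)
  env_d <- Mod(a)
  ph_d <- Arg(a)

  n <- length(x)
  if (q > 1L) {
    td <- (seq_along(xd) - 1) / fsd
    tt <- (seq_len(n) - 1) / fs
    filtered <- approx(td, fd, xout = tt, rule = 2)$y
    envelope <- approx(td, env_d, xout = tt, rule = 2)$y
    ph_un <- unwrap_phase(ph_d)
    phase <- wrap_pi(approx(td, ph_un, xout = tt, rule = 2)$y)
  } else {
    filtered <- fd; envelope <- env_d; phase <- ph_d
  }
  structure(
    list(band = as.numeric(band), filtered = filtered, amplitude = envelope,
         phase = phase, envelope = envelope, rate_hz = fs, t0 = t0),
    class = "band_signal")
}

#' @export
print.band_signal <- function(x, ...) {
  cat(sprintf("<band_signal %g-%g Hz: %d samples @ %g Hz>\n",
              x$band[1], x$band[2], length(x$filtered), x$rate_hz))
  invisible(x)
}

# FFT brick-wall low-pass then subsample by integer factor q.
decimate_fft <- function(x, q) {
  p <- pad_fast(x)
  n <- length(p$x)
  X <- fft(p$x)
  cut <- floor(n / (2 * q) * 0.9)
  keep <- rep(FALSE, n)
  keep[1:(cut + 1)] <- TRUE
  keep[(n - cut + 1):n] <- TRUE
  x_lp <- Re(fft(X * keep, inverse = TRUE) / n)[seq_len(p$n)]
  x_lp[seq(1, p$n, by = q)]
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Sample times of a band signal.
band_times <- function(bsig) {
  bsig$t0 + (seq_along(bsig$filtered) - 1) / bsig$rate_hz
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal formulation; returns an n x k matrix of unit-norm tapers.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * ((n - 1):1) / 2
  # full symmetric tridiagonal matrix eigen-decomposition
  A <- diag(d)
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # conventional polarity: positive mean for symmetric tapers
  for (j in seq_len(k)) {
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  v
}

# Multitaper spectral matrix for one data window across trials.
# x: matrix n x n_trials. Returns list(freqs, power [freq x trial]).
mt_power_one <- function(x, fs, tapers) {
  n <- nrow(x)
  k <- ncol(tapers)
  nf <- floor(n / 2) + 1
  pow <- matrix(0, nf, ncol(x))
  for (j in seq_len(k)) {
    tx <- x * tapers[, j]
    X <- stats::mvfft(tx)
    pow <- pow + Mod(X[1:nf, , drop = FALSE])^2
  }
  list(freqs = (0:(nf - 1)) * fs / n, power = pow / (k * fs))
}

#' Event-aligned multitaper spectrogram
#'
#' Trial-averaged multitaper power in sliding windows around alignment
#' events. Defaults: 500 ms windows, 50 ms step, time-bandwidth product 3
#' with 5 Slepian tapers. Optionally z-scores each frequency row against
#' its mean/sd across the whole aligned epoch.
#'
#' @param sig An [lfp_signal()].
#' @param events Numeric vector of alignment times (s).
#' @param pre_s,post_s Epoch extent before/after each event (s).
#' @param window_s,step_s Sliding-window length and step (s).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2 * nw - 1`).
#' @param zscore Z-score per frequency row against the epoch.
#' @param fmax Keep frequencies up to `fmax` Hz.
#' @return A `time_freq_result`: list with `times` (window centers relative
#'   to the event), `freqs`, `values` (freq x time matrix), `zscored`,
#'   `kind = "power"`.
#' @export
multitaper_spectrogram <- function(sig, events, pre_s = 1, post_s = 1,
                                   window_s = 0.5, step_s = 0.05, nw = 3,
                                   k = 2 * nw - 1, zscore = TRUE,
                                   fmax = 100) {
  if (length(events) < 1) abort("At least one alignment event is required.")
  fs <- sig$rate_hz
  nwin <- round(window_s * fs)
  if (nwin < 2 * nw) abort("Window too short for the requested bandwidth.")
  tapers <- dpss_tapers(nwin, nw, k)
  centers <- seq(-pre_s, post_s, by = step_s)
  tvec <- lfp_times(sig)

  segs <- extract_segments(sig$samples, tvec, events, centers, nwin, fs)
  nf <- floor(nwin / 2) + 1
  freqs <- (0:(nf - 1)) * fs / nwin
  sel <- freqs <= fmax
  vals <- matrix(NA_real_, sum(sel), length(centers))
  for (ci in seq_along(centers)) {
    x <- segs[[ci]]
    if (is.null(x) || ncol(x) == 0) next
    mp <- mt_power_one(x, fs, tapers)
    vals[, ci] <- rowMeans(mp$power[sel, , drop = FALSE])
  }
  if (zscore) vals <- t(scale(t(vals)))
  structure(list(times = centers, freqs = freqs[sel], values = vals,
                 zscored = zscore, kind = "power"),
            class = "time_freq_result")
}

# Cut event-centered windows; returns per-center matrices nwin x n_events.
extract_segments <- function(x, tvec, events, centers, nwin, fs) {
  n <- length(x)
  t0 <- tvec[1]
  lapply(centers, function(ct) {
    starts <- round((events + ct - nwin / (2 * fs) - t0) * fs) + 1
    ok <- starts >= 1 & (starts + nwin - 1) <= n
    if (!any(ok)) return(NULL)
    vapply(starts[ok], function(s0) x[s0:(s0 + nwin - 1)], numeric(nwin))
  })
}

#' Event-aligned multitaper coherogram
#'
#' Magnitude-squared coherence between two simultaneously recorded LFP
#' signals, per time-frequency cell, with trial (event) averaging of the
#' cross- and auto-spectra across both events and tapers.
#'
#' @inheritParams multitaper_spectrogram
#' @param sigA,sigB Two [lfp_signal()]s at the same rate.
#' @return A `time_freq_result` with `kind = "coherence"`; values lie in
#'   `[0, 1]` before z-scoring.
#' @export
multitaper_coherogram <- function(sigA, sigB, events, pre_s = 1, post_s = 1,
                                  window_s = 0.5, step_s = 0.05, nw = 3,
                                  k = 2 * nw - 1, zscore = FALSE,
                                  fmax = 100) {
  if (sigA$rate_hz != sigB$rate_hz) abort("Signals must share a rate.")
  if (length(sigA$samples) != length(sigB$samples)) {
    abort("Signals must have equal length.")
  }
  if (length(events) < 1) abort("At least one alignment event is required.")
  fs <- sigA$rate_hz
  nwin <- round(window_s * fs)
  tapers <- dpss_tapers(nwin, nw, k)
  centers <- seq(-pre_s, post_s, by = step_s)
  tvec <- lfp_times(sigA)
  segA <- extract_segments(sigA$samples, tvec, events, centers, nwin, fs)
  segB <- extract_segments(sigB$samples, tvec, events, centers, nwin, fs)
  nf <- floor(nwin / 2) + 1
  freqs <- (0:(nf - 1)) * fs / nwin
  sel <- freqs <= fmax
  vals <- matrix(NA_real_, sum(sel), length(centers))
  for (ci in seq_along(centers)) {
    xa <- segA[[ci]]; xb <- segB[[ci]]
    if (is.null(xa) || is.null(xb)) next
    sxx <- syy <- matrix(0, nf, 1)
    sxy <- matrix(complex(real = 0), nf, 1)
    for (j in seq_len(ncol(tapers))) {
      A <- stats::mvfft(xa * tapers[, j])[1:nf, , drop = FALSE]
      B <- stats::mvfft(xb * tapers[, j])[1:nf, , drop = FALSE]
      sxx <- sxx + rowSums(Mod(A)^2)
      syy <- syy + rowSums(Mod(B)^2)
      sxy <- sxy + rowSums(A * Conj(B))
    }
    vals[, ci] <- (Mod(sxy)^2 / (sxx * syy))[sel]
  }
  if (zscore) vals <- t(scale(t(vals)))
  structure(list(times = centers, freqs = freqs[sel], values = vals,
                 zscored = zscore, kind = "coherence"),
            class = "time_freq_result")
}

#' Mean band power/coherence in a time-frequency box
#'
#' Convenience summary of a `time_freq_result` over a band and a time
#' range; used to build per-session condition summaries.
#'
#' @param tfr A `time_freq_result`.
#' @param band Length-2 Hz range.
#' @param t_range Length-2 time range relative to the alignment event.
#' @return Scalar mean value.
#' @export
band_mean <- function(tfr, band, t_range = range(tfr$times)) {
  fi <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  ti <- tfr$times >= t_range[1] & tfr$times <= t_range[2]
  mean(tfr$values[fi, ti], na.rm = TRUE)
}

#' Paired condition contrast across sessions
#'
#' Wilcoxon signed-rank test on within-session differences of a band
#' summary between two conditions (e.g. post- vs pre-odor beta power).
#' Sessions missing either condition are dropped with a warning. For
#' correct-vs-incorrect contrasts the caller is expected to have
#' trial-count matched the conditions (see
#' [match_trial_counts()]).
#'
#' @param df Data frame with columns `session`, `a`, `b` (per-session
#'   summaries for conditions A and B).
#' @param alternative Test direction for B - A differences (`"two.sided"`,
#'   `"greater"` = B > A, `"less"`).
#' @return A tibble of class `contrast_result` with `statistic` (signed-rank
#'   V), `p`, `n_sessions`, `mean_delta`, and the per-session deltas in
#'   `attr(, "deltas")`.
#' @export
condition_contrast <- function(df, alternative = "two.sided") {
  keep <- complete.cases(df[, c("a", "b")])
  if (any(!keep)) {
    warn(sprintf("%d session(s) dropped: missing a condition.", sum(!keep)))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2) abort("At least two complete sessions are required.")
  delta <- df$b - df$a
  if (all(delta == 0)) {
    wt <- list(statistic = c(V = 0), p.value = 1)
  } else {
    wt <- suppressWarnings(
      wilcox.test(df$b, df$a, paired = TRUE, alternative = alternative))
  }
  out <- tibble(statistic = unname(wt$statistic), p = wt$p.value,
                n_sessions = nrow(df), mean_delta = mean(delta))
  attr(out, "deltas") <- delta
  class(out) <- c("contrast_result", class(out))
  out
}

#' Match trial counts between conditions
#'
#' Draws a single seeded random subsample of the larger condition to the
#' size of the smaller, used before correct-vs-incorrect comparisons.
#'
#' @param idx_large,idx_small Index vectors for the two conditions.
#' @return Subsampled `idx_large` of length `length(idx_small)`.
#' @export
match_trial_counts <- function(idx_large, idx_small) {
  if (length(idx_large) <= length(idx_small)) return(idx_large)
  sample(idx_large, length(idx_small))
}

#' Bootstrap down-sampling test (odor vs air)
#'
#' Compares per-trial values on odor-cued trials against a much smaller set
#' of air (uncued) trials. Odor trials are down-sampled with replacement to
#' the number of air trials; the mean of each of `n_boot` such resamples
#' forms a bootstrap distribution, and the one-sided p-value is the
#' fraction of bootstrap means at or below the observed air mean (testing
#' air < odor).
#'
#' @param odor_values,air_values Per-trial values.
#' @param n_boot Number of resamples (default 1000).
#' @param alternative `"air_less"` (default, one-sided) or `"two.sided"`.
#' @return A tibble with `p`, `p_label` (reports `"< 1/n_boot"` at the
#'   resolution floor), `odor_mean`, `air_mean`, and the bootstrap means in
#'   `attr(, "boot")`.
#' @export
bootstrap_downsample_test <- function(odor_values, air_values, n_boot = 1000,
                                      alternative = c("air_less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(air_values) < 1) abort("Need at least one air trial.")
  if (length(odor_values) < length(air_values)) {
    abort("Odor trials must be at least as numerous as air trials.")
  }
  if (n_boot < 100) warn("Fewer than 100 bootstrap resamples is unreliable.")
  n_air <- length(air_values)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(odor_values, n_air, replace = TRUE))
  }, numeric(1))
  air_mean <- mean(air_values)
  frac_le <- sum(boot <= air_mean) / n_boot
  p <- if (alternative == "air_less") frac_le else
    2 * min(frac_le, sum(boot >= air_mean) / n_boot)
  p_label <- if (p == 0) sprintf("< %g", 1 / n_boot) else
    format(p, digits = 3)
  out <- tibble(p = p, p_label = p_label, odor_mean = mean(odor_values),
                air_mean = air_mean, n_odor = length(odor_values),
                n_air = n_air)
  attr(out, "boot") <- boot
  out
}

#' Cross-region band phase offset
#'
#' Circular summary of per-sample phase differences between two band
#' signals within a set of analysis windows (typically odor-sampling
#' periods).
#'
#' @param bsigA,bsigB Two [bandpass_zero_phase()] outputs at the same rate.
#' @param windows Matrix/data frame of `(start, end)` windows (s).
#' @return A tibble with `mean_offset` (rad, A relative to B, wrapped to
#'   `[-pi, pi)`), `resultant` (circular concentration in `[0, 1]`), and
#'   `n_samples`.
#' @export
cross_region_phase_offset <- function(bsigA, bsigB, windows) {
  if (bsigA$rate_hz != bsigB$rate_hz) abort("Signals must share a rate.")
  windows <- check_windows(windows)
  t <- band_times(bsigA)
  sel <- in_windows(t, windows)
  if (!any(sel)) abort("No samples fall inside the windows.")
  d <- wrap_pi(bsigA$phase[sel] - bsigB$phase[sel])
  z <- mean(exp(1i * d))
  tibble(mean_offset = Arg(z), resultant = Mod(z), n_samples = sum(sel))
}
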