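#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_col geom_ribbon
#'   geom_hline geom_point geom_errorbar scale_fill_viridis_c labs autoplot
#'   theme_minimal coord_polar
NULL

#' Plot a time-frequency result
#'
#' @param object A `time_freq_result` from [multitaper_spectrogram()] or
#'   [multitaper_coherogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot time_freq_result
#' @export
autoplot.time_freq_result <- function(object, ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$value <- as.vector(object$values)
  ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (object$zscored) "z" else object$kind) +
    labs(x = "time from event (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot a phase-amplitude coupling profile
#'
#' @param object A `pac_result` from [pac_modulation_index()] or
#'   [pac_null()].
#' @param ... Unused.
#' @return A ggplot of normalized beta amplitude per RR phase bin.
#' @method autoplot pac_result
#' @export
autoplot.pac_result <- function(object, ...) {
  P <- attr(object, "profile")
  edges <- attr(object, "edges")
  df <- tibble(phase_deg = (edges[-1] + edges[-length(edges)]) / 2 * 180 / pi,
               norm_amplitude = P)
  ggplot(df, aes(x = .data$phase_deg, y = .data$norm_amplitude)) +
    geom_col(width = 18, fill = "steelblue") +
    geom_hline(yintercept = 1 / length(P), linetype = 2) +
    labs(x = "RR phase (deg)", y = "normalized beta amplitude",
         subtitle = sprintf("MI = %.4f", object$mi)) +
    theme_minimal()
}

#' Plot a jitter-corrected cross-correlogram
#'
#' @param object A `ccg_result` from [jitter_corrected_ccg()].
#' @param ... Unused.
#' @return A ggplot of the pointwise z-scored CCG; positive lags mean the
#'   reference (CA1) cell leads.
#' @method autoplot ccg_result
#' @export
autoplot.ccg_result <- function(object, ...) {
  df <- tibble(lag_ms = object$lags_ms, z = object$z)
  ggplot(df, aes(x = .data$lag_ms, y = .data$z)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "lag (ms), positive = CA1 leads", y = "z vs jitter null",
         subtitle = sprintf("peak %.1f ms, p = %.3g", object$peak_lag_ms,
                            object$p)) +
    theme_minimal()
}

#' Plot a linearized tuning curve
#'
#' @param object A `linear_tuning_curve`.
#' @param ... Unused.
#' @return A ggplot of rate vs linear position.
#' @method autoplot linear_tuning_curve
#' @export
autoplot.linear_tuning_curve <- function(object, ...) {
  df <- tibble(pos_cm = object$bin_centers, rate = object$rate)
  ggplot(df, aes(x = .data$pos_cm, y = .data$rate)) +
    geom_line() +
    labs(x = "linear position (cm)", y = "rate (Hz)",
         subtitle = object$route) +
    theme_minimal()
}

#' Plot PCA trajectory discrimination
#'
#' @param object A `trajectory_discrimination` from [pca_discrimination()].
#' @param ... Unused.
#' @return A ggplot of the left-right trajectory distance with the
#'   shuffle 95% band and the even/odd control.
#' @method autoplot trajectory_discrimination
#' @export
autoplot.trajectory_discrimination <- function(object, ...) {
  df <- tibble(time_s = object$bin_centers_s, dist = object$dist,
               ci95 = object$null_ci95, evenodd = object$evenodd_dist)
  ggplot(df, aes(x = .data$time_s)) +
    geom_ribbon(aes(ymin = 0, ymax = .data$ci95), alpha = 0.2) +
    geom_line(aes(y = .data$dist), linewidth = 1) +
    geom_line(aes(y = .data$evenodd), linetype = 3) +
    labs(x = "time from odor onset (s)",
         y = "PC trajectory distance (L vs R)") +
    theme_minimal()
}

#' Plot quintile decoding accuracy
#'
#' @param object A `quintile_decoding` from [decode_choice_by_quintile()].
#' @param ... Unused.
#' @return A ggplot of decoding accuracy per spatial quintile with the
#'   shuffle mean +/- sd.
#' @method autoplot quintile_decoding
#' @export
autoplot.quintile_decoding <- function(object, ...) {
  ggplot(object, aes(x = .data$quintile)) +
    geom_errorbar(aes(ymin = .data$null_mean - .data$null_sd,
                      ymax = .data$null_mean + .data$null_sd),
                  width = 0.2, colour = "grey60") +
    geom_point(aes(y = .data$null_mean), colour = "grey60") +
    geom_point(aes(y = .data$accuracy), colour = "firebrick", size = 2) +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "spatial quintile (24.6 cm each)", y = "decoding accuracy") +
    theme_minimal()
}

#' Spike-phase histogram
#'
#' @param phases Spike phases (rad).
#' @param n_bins Number of phase bins.
#' @return A polar ggplot of the spike-phase histogram.
#' @export
plot_phase_histogram <- function(phases, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(wrap_pi(phases), edges,
                               rightmost.closed = TRUE), nbins = n_bins)
  df <- tibble(phase_deg = (edges[-1] + edges[-length(edges)]) / 2 * 180 / pi,
               count = cnt)
  ggplot(df, aes(x = .data$phase_deg, y = .data$count)) +
    geom_col(width = 360 / n_bins, fill = "steelblue") +
    coord_polar(start = pi) +
    labs(x = "band phase (deg; 0 = oscillation peak)", y = "spikes") +
    theme_minimal()
}
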