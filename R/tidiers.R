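#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a time-frequency result
#'
#' @param x A `time_freq_result`.
#' @param ... Unused.
#' @return A long tibble with `time`, `freq`, `value`.
#' @method tidy time_freq_result
#' @export
tidy.time_freq_result <- function(x, ...) {
  df <- tidyr::expand_grid(freq = x$freqs, time = x$times)
  df$value <- as.vector(x$values)
  df[, c("time", "freq", "value")]
}

#' @rdname tidy.time_freq_result
#' @method glance time_freq_result
#' @export
glance.time_freq_result <- function(x, ...) {
  tibble(kind = x$kind, zscored = x$zscored,
         n_times = length(x$times), n_freqs = length(x$freqs),
         max_value = max(x$values, na.rm = TRUE),
         min_value = min(x$values, na.rm = TRUE))
}

#' Tidy a jitter-corrected CCG
#'
#' @param x A `ccg_result`.
#' @param ... Unused.
#' @return A tibble with `lag_ms`, `raw`, `z`, `smoothed`.
#' @method tidy ccg_result
#' @export
tidy.ccg_result <- function(x, ...) {
  tibble(lag_ms = x$lags_ms, raw = x$raw, z = x$z, smoothed = x$smoothed)
}

#' @rdname tidy.ccg_result
#' @method glance ccg_result
#' @export
glance.ccg_result <- function(x, ...) {
  tibble(peak_lag_ms = x$peak_lag_ms, peak_z = x$peak_z, p = x$p,
         significant = x$significant, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a PCA trajectory discrimination
#'
#' @param x A `trajectory_discrimination`.
#' @param ... Unused.
#' @return A tibble with `time_s`, `dist`, `null_ci95`, `evenodd_dist`.
#' @method tidy trajectory_discrimination
#' @export
tidy.trajectory_discrimination <- function(x, ...) {
  tibble(time_s = x$bin_centers_s, dist = x$dist, null_ci95 = x$null_ci95,
         evenodd_dist = x$evenodd_dist)
}

#' @rdname tidy.trajectory_discrimination
#' @method glance trajectory_discrimination
#' @export
glance.trajectory_discrimination <- function(x, ...) {
  tibble(discrimination_time_s = x$discrimination_time_s, n_pc = x$n_pc)
}

#' Tidy a linearized tuning curve
#'
#' @param x A `linear_tuning_curve`.
#' @param ... Unused.
#' @return A tibble with `pos_cm`, `rate`, `rate_raw`, `occupancy`.
#' @method tidy linear_tuning_curve
#' @export
tidy.linear_tuning_curve <- function(x, ...) {
  tibble(pos_cm = x$bin_centers, rate = x$rate, rate_raw = x$rate_raw,
         occupancy = x$occupancy)
}

#' @rdname tidy.linear_tuning_curve
#' @method glance linear_tuning_curve
#' @export
glance.linear_tuning_curve <- function(x, ...) {
  fs <- field_stats(x)
  fs$route <- x$route
  fs$n_runs <- x$n_runs
  fs
}
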