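#' Session data model
#'
#' A session record bundles everything recorded in one behavioral session on
#' one shared clock (seconds, starting at 0): local field potentials per
#' region/tetrode, per-unit spike trains, the trial table, the position
#' trace, and an optional nasal thermocouple trace. Region labels are drawn
#' from the controlled vocabulary CA1, PFC, OB.
#'
#' All time intervals in the package are half-open `[start, end)`: a spike
#' at exactly the odor-port exit time belongs to the next interval, never to
#' the odor period. Bins are 0-based: bin `b` covers `[b * delta, (b + 1) *
#' delta)`.
#'
#' @name session-model
NULL

REGIONS <- c("CA1", "PFC", "OB")

#' Construct an LFP signal
#'
#' @param region Region label, one of `"CA1"`, `"PFC"`, `"OB"`.
#' @param tetrode_id Integer tetrode identifier.
#' @param rate_hz Sampling rate in Hz (nominally 1500).
#' @param samples Numeric vector of LFP samples (arbitrary units).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(region, tetrode_id, rate_hz, samples, t0 = 0) {
  region <- match.arg(region, REGIONS)
  if (rate_hz <= 0) abort("`rate_hz` must be positive.")
  if (!all(is.finite(samples))) abort("LFP samples must be finite.")
  structure(
    list(region = region, tetrode_id = as.integer(tetrode_id),
         rate_hz = as.numeric(rate_hz), samples = as.numeric(samples),
         t0 = as.numeric(t0)),
    class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal %s tt%02d: %d samples @ %g Hz, t0 = %g s>\n",
              x$region, x$tetrode_id, length(x$samples), x$rate_hz, x$t0))
  invisible(x)
}

# Sample times of an LFP signal.
lfp_times <- function(sig) {
  sig$t0 + (seq_along(sig$samples) - 1) / sig$rate_hz
}

#' Construct a spike train
#'
#' @param unit_id Integer unit identifier.
#' @param region Region label.
#' @param tetrode_id Integer tetrode the unit was isolated on.
#' @param spike_times Nondecreasing numeric vector of spike times (s).
#' @param mean_rate_hz Session-wide mean firing rate (Hz).
#' @param spike_width_ms Average spike width (ms); used with the mean rate
#'   to separate putative interneurons (> 7 Hz and < 0.3 ms) from pyramidal
#'   cells.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, region, tetrode_id, spike_times,
                        mean_rate_hz = NA_real_, spike_width_ms = NA_real_) {
  region <- match.arg(region, REGIONS)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) abort("`spike_times` must be nondecreasing.")
  if (!is.na(mean_rate_hz) && mean_rate_hz < 0) {
    abort("`mean_rate_hz` must be nonnegative.")
  }
  structure(
    list(unit_id = as.integer(unit_id), region = region,
         tetrode_id = as.integer(tetrode_id), spike_times = spike_times,
         mean_rate_hz = as.numeric(mean_rate_hz),
         spike_width_ms = as.numeric(spike_width_ms)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train unit %d (%s tt%02d): %d spikes, %.2f Hz, width %.2f ms>\n",
              x$unit_id, x$region, x$tetrode_id, length(x$spike_times),
              x$mean_rate_hz, x$spike_width_ms))
  invisible(x)
}

#' Construct a trial table
#'
#' One row per trial of the two-odor T-maze task. Odor 1 is associated with
#' the left reward arm and odor 2 with the right arm; `correct` is `TRUE`
#' when the chosen arm matches the odor-assigned arm.
#'
#' @param df Data frame with columns `trial_id`, `odor` (1 or 2),
#'   `port_in`, `port_out` (odor-port beam-break times, s), `choice` (1 or
#'   2), `correct` (logical), `reward_in`, `reward_out` (reward-well times,
#'   s, `NA` when the well was not visited), and optionally `included`.
#' @return A tibble with class `trial_table`, with `included` recomputed via
#'   [exclude_premature_trials()] if absent.
#' @export
trial_table <- function(df) {
  need <- c("trial_id", "odor", "port_in", "port_out", "choice", "correct",
            "reward_in", "reward_out")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("Trial table is missing columns: ", paste(miss, collapse = ", ")))
  }
  df <- as_tibble(df)
  bad <- which(df$port_out <= df$port_in)
  if (length(bad) > 0) {
    abort(sprintf("Trial %s has port_out <= port_in.",
                  paste(df$trial_id[bad], collapse = ", ")))
  }
  if (!all(df$odor %in% c(1, 2)) || !all(df$choice %in% c(1, 2))) {
    abort("`odor` and `choice` must be 1 or 2.")
  }
  if (!"included" %in% names(df)) {
    df <- exclude_premature_trials(df)
  }
  class(df) <- c("trial_table", class(df))
  df
}

#' Flag prematurely terminated trials
#'
#' Trials in which the animal held its nose in the odor port for less than
#' the minimum hold (0.50 s, inclusive threshold) or never went on to visit
#' a reward well are excluded from every downstream analysis.
#'
#' @param trials Trial table (data frame).
#' @param min_hold_s Minimum odor-port hold duration in seconds.
#' @return The table with a logical `included` column.
#' @export
exclude_premature_trials <- function(trials, min_hold_s = 0.5) {
  trials <- as_tibble(trials)
  hold <- trials$port_out - trials$port_in
  visited_reward <- !is.na(trials$reward_in)
  trials$included <- hold >= min_hold_s & visited_reward
  trials
}

# Included trials only; shared filter for downstream analyses.
included_trials <- function(trials) {
  trials[trials$included, , drop = FALSE]
}

# Odor-period windows [port_in, port_out) of included trials, as a matrix.
odor_windows <- function(trials, included_only = TRUE) {
  tr <- if (included_only) included_trials(trials) else trials
  cbind(start = tr$port_in, end = tr$port_out)
}

#' Construct a position trace
#'
#' Speed, when not supplied, is derived by central differences of the
#' Gaussian-smoothed (sigma = 2 samples) x/y coordinates.
#'
#' @param t Sample times (s).
#' @param x,y Coordinates in cm.
#' @param speed Optional speed in cm/s; derived if `NULL`.
#' @return A tibble with class `position_trace` and columns `t, x, y, speed`.
#' @export
position_trace <- function(t, x, y, speed = NULL) {
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    abort("`t`, `x`, `y` must have equal length.")
  }
  if (is.null(speed)) speed <- derive_speed(t, x, y)
  out <- tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                speed = pmax(0, as.numeric(speed)))
  class(out) <- c("position_trace", class(out))
  out
}

# Central-difference speed on smoothed coordinates.
derive_speed <- function(t, x, y, sigma_samples = 2) {
  n <- length(t)
  if (n < 3L) return(rep(0, n))
  xs <- gauss_smooth(x, sigma_samples)
  ys <- gauss_smooth(y, sigma_samples)
  vx <- numeric(n); vy <- numeric(n)
  dt <- t[3:n] - t[1:(n - 2)]
  vx[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) / dt
  vy[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / dt
  vx[1] <- vx[2]; vx[n] <- vx[n - 1]
  vy[1] <- vy[2]; vy[n] <- vy[n - 1]
  sqrt(vx^2 + vy^2)
}

#' Construct a session record
#'
#' @param session_id Character identifier.
#' @param lfp List of [lfp_signal()] objects.
#' @param units List of [spike_train()] objects.
#' @param trials A [trial_table()].
#' @param position A [position_trace()].
#' @param thermocouple Optional tibble with columns `t`, `value` (nasal
#'   thermocouple, arbitrary units proportional to airflow temperature).
#' @param epochs Optional tibble with columns `label`, `start`, `end`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, lfp, units, trials, position,
                           thermocouple = NULL, epochs = NULL,
                           validate = TRUE) {
  rec <- structure(
    list(session_id = as.character(session_id), lfp = lfp, units = units,
         trials = trials, position = position, thermocouple = thermocouple,
         epochs = epochs),
    class = "session_record")
  if (validate) validate_session(rec)
  rec
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record '%s': %d LFP channels, %d units, %d trials (%d included)>\n",
              x$session_id, length(x$lfp), length(x$units),
              nrow(x$trials), sum(x$trials$included)))
  invisible(x)
}

#' Validate a session record
#'
#' Checks the data-model invariants: regions in the controlled vocabulary,
#' positive sampling rates, finite LFP samples, sorted spike times, trial
#' interval ordering, and clock consistency (no spike later than the LFP
#' support plus one sample period).
#'
#' @param session A `session_record`.
#' @return The session, invisibly; aborts with an informative message on the
#'   first violated invariant, naming the offending trial or unit.
#' @export
validate_session <- function(session) {
  for (sig in session$lfp) {
    if (!sig$region %in% REGIONS) {
      abort(sprintf("LFP region '%s' not in {%s}.", sig$region,
                    paste(REGIONS, collapse = ", ")))
    }
    if (sig$rate_hz <= 0) abort("LFP rate must be positive.")
    if (!all(is.finite(sig$samples))) {
      abort(sprintf("LFP %s tt%02d has non-finite samples.",
                    sig$region, sig$tetrode_id))
    }
  }
  for (u in session$units) {
    if (!u$region %in% REGIONS) {
      abort(sprintf("Unit %d region '%s' invalid.", u$unit_id, u$region))
    }
    if (is.unsorted(u$spike_times)) {
      abort(sprintf("Unit %d spike times are not sorted.", u$unit_id))
    }
  }
  tr <- session$trials
  bad <- which(tr$port_out <= tr$port_in)
  if (length(bad) > 0) {
    abort(sprintf("Trial %s violates port_out > port_in.",
                  paste(tr$trial_id[bad], collapse = ", ")))
  }
  pos <- session$position
  if (any(pos$speed < 0)) abort("Position speed must be nonnegative.")
  if (length(session$lfp) > 0 && length(session$units) > 0) {
    max_lfp <- max(vapply(session$lfp, function(s) {
      s$t0 + (length(s$samples) - 1) / s$rate_hz + 1 / s$rate_hz
    }, numeric(1)))
    max_spk <- suppressWarnings(
      max(vapply(session$units,
                 function(u) if (length(u$spike_times)) max(u$spike_times) else -Inf,
                 numeric(1))))
    if (is.finite(max_spk) && max_spk > max_lfp) {
      abort("Spike times extend past the LFP support.")
    }
  }
  if (!is.null(session$epochs) && nrow(session$epochs) > 1) {
    ep <- session$epochs[order(session$epochs$start), ]
    if (any(ep$start[-1] < ep$end[-nrow(ep)])) {
      abort("Epoch intervals must be disjoint.")
    }
  }
  invisible(session)
}

#' Save a session bundle
#'
#' Writes a session record to a directory of plain-text files:
#' `trials.csv`, `position.csv`, `lfp_meta.csv` plus one
#' `lfp_REGION_ttNN.csv` per channel, `units.csv` plus one
#' `spikes_unitNN.csv` per unit, and optionally `thermocouple.csv` and
#' `epochs.csv`. The CSV parts are byte-stable under write-read-write.
#'
#' @param session A `session_record`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create bundle directory '%s'.", path))
  }
  # doubles are written as %.17g so that write -> read -> write is
  # byte-stable (17 significant digits round-trip IEEE doubles exactly)
  wcsv <- function(df, file) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) {
        v <- sprintf("%.17g", df[[j]])
        v[is.na(df[[j]])] <- NA_character_
        df[[j]] <- v
      }
    }
    readr::write_csv(df, file.path(path, file), progress = FALSE)
  }
  tr <- as_tibble(session$trials)[, c("trial_id", "odor", "port_in", "port_out",
                                      "choice", "correct", "reward_in",
                                      "reward_out", "included")]
  wcsv(tr, "trials.csv")
  wcsv(as_tibble(session$position), "position.csv")

  lfp_meta <- purrr::map_dfr(session$lfp, function(s) {
    tibble(region = s$region, tetrode_id = s$tetrode_id, rate_hz = s$rate_hz,
           t0 = s$t0, n_samples = length(s$samples),
           file = sprintf("lfp_%s_tt%02d.csv", s$region, s$tetrode_id))
  })
  wcsv(lfp_meta, "lfp_meta.csv")
  for (s in session$lfp) {
    wcsv(tibble(sample = s$samples),
         sprintf("lfp_%s_tt%02d.csv", s$region, s$tetrode_id))
  }

  unit_meta <- purrr::map_dfr(session$units, function(u) {
    tibble(unit_id = u$unit_id, region = u$region, tetrode_id = u$tetrode_id,
           mean_rate_hz = u$mean_rate_hz, spike_width_ms = u$spike_width_ms,
           n_spikes = length(u$spike_times),
           file = sprintf("spikes_unit%03d.csv", u$unit_id))
  })
  if (nrow(unit_meta) == 0) {
    unit_meta <- tibble(unit_id = integer(), region = character(),
                        tetrode_id = integer(), mean_rate_hz = numeric(),
                        spike_width_ms = numeric(), n_spikes = integer(),
                        file = character())
  }
  wcsv(unit_meta, "units.csv")
  for (u in session$units) {
    wcsv(tibble(spike_time = u$spike_times),
         sprintf("spikes_unit%03d.csv", u$unit_id))
  }

  if (!is.null(session$thermocouple)) {
    wcsv(as_tibble(session$thermocouple), "thermocouple.csv")
  }
  if (!is.null(session$epochs)) {
    wcsv(as_tibble(session$epochs), "epochs.csv")
  }
  wcsv(tibble(session_id = session$session_id), "session.csv")
  invisible(path)
}

#' Load a session bundle
#'
#' Inverse of [save_session()]; validates all invariants on load.
#'
#' @param path Bundle directory written by [save_session()].
#' @return A validated `session_record`.
#' @export
load_session <- function(path) {
  need <- c("trials.csv", "position.csv", "lfp_meta.csv", "units.csv",
            "session.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("Bundle at '%s' is missing '%s'.", path, f))
    }
  }
  # base read.csv: strtod parsing is correctly rounded, so %.17g-formatted
  # doubles round-trip bit-exactly (readr's fast float path can be 1 ulp off)
  rcsv <- function(file) {
    as_tibble(utils::read.csv(file.path(path, file)))
  }
  trials <- trial_table(rcsv("trials.csv"))
  posdf <- rcsv("position.csv")
  position <- position_trace(posdf$t, posdf$x, posdf$y, speed = posdf$speed)

  lfp_meta <- rcsv("lfp_meta.csv")
  lfp <- purrr::pmap(lfp_meta, function(region, tetrode_id, rate_hz, t0,
                                        n_samples, file) {
    if (!file.exists(file.path(path, file))) {
      abort(sprintf("Bundle is missing LFP file '%s'.", file))
    }
    lfp_signal(region, tetrode_id, rate_hz, rcsv(file)$sample, t0)
  })

  unit_meta <- rcsv("units.csv")
  units <- if (nrow(unit_meta) == 0) list() else {
    purrr::pmap(unit_meta, function(unit_id, region, tetrode_id, mean_rate_hz,
                                    spike_width_ms, n_spikes, file) {
      if (!file.exists(file.path(path, file))) {
        abort(sprintf("Bundle is missing spike file '%s' for unit %d.",
                      file, unit_id))
      }
      spike_train(unit_id, region, tetrode_id, rcsv(file)$spike_time,
                  mean_rate_hz, spike_width_ms)
    })
  }

  thermo <- if (file.exists(file.path(path, "thermocouple.csv"))) {
    rcsv("thermocouple.csv")
  } else NULL
  epochs <- if (file.exists(file.path(path, "epochs.csv"))) {
    rcsv("epochs.csv")
  } else NULL
  sid <- rcsv("session.csv")$session_id[1]
  session_record(sid, lfp, units, trials, position, thermo, epochs)
}
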