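#' Run-epoch extraction
#'
#' Maximal contiguous intervals in which running speed exceeds a threshold
#' (3 cm/s by default, the conventional immobility cutoff).
#'
#' @param position A [position_trace()].
#' @param speed_thresh Speed threshold in cm/s.
#' @return A tibble with columns `start`, `end` (half-open intervals, s).
#' @export
run_epochs <- function(position, speed_thresh = 3) {
  fast <- position$speed > speed_thresh
  if (!any(fast)) return(tibble(start = numeric(), end = numeric()))
  r <- rle(fast)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- r$values
  t <- position$t
  dt <- median(diff(t))
  tibble(start = t[starts_idx[keep]],
         end = t[ends_idx[keep]] + dt)
}

#' Sharp-wave ripple detection
#'
#' Filters each CA1 channel in the ripple band (150-250 Hz), takes the
#' Hilbert envelope (smoothed with a 4 ms Gaussian), and flags contiguous
#' periods in which the envelope exceeds mean + 3 SD for at least 15 ms on
#' at least one tetrode. Event boundaries are extended outward to where
#' the envelope falls back to the mean; overlapping per-tetrode events are
#' merged. Because the threshold is in SD units, detection is invariant to
#' amplitude scaling of the trace.
#'
#' @param lfp_list List of CA1 [lfp_signal()]s sampled at >= 600 Hz.
#' @param band Ripple band (Hz).
#' @param sd_thresh Threshold in SDs above the mean envelope.
#' @param min_dur_s Minimum supra-threshold duration (s).
#' @return A tibble of class `swr_events` with `tetrode_id`, `start`,
#'   `end`, `peak_z` (peak envelope in SD units).
#' @export
detect_swr <- function(lfp_list, band = c(150, 250), sd_thresh = 3,
                       min_dur_s = 0.015) {
  if (inherits(lfp_list, "lfp_signal")) lfp_list <- list(lfp_list)
  if (length(lfp_list) < 1) abort("At least one CA1 channel is required.")
  per_tt <- purrr::map_dfr(lfp_list, function(sig) {
    if (sig$rate_hz < 2.4 * band[2]) {
      abort(sprintf("Rate %g Hz too low for the %g-%g Hz ripple band.",
                    sig$rate_hz, band[1], band[2]))
    }
    bs <- bandpass_zero_phase(sig, band)
    env <- gauss_smooth(bs$envelope, sigma = 0.004 * sig$rate_hz)
    mu <- mean(env); sdv <- sd(env)
    z <- (env - mu) / sdv
    core <- z > sd_thresh
    if (!any(core)) {
      return(tibble(tetrode_id = integer(), start = numeric(),
                    end = numeric(), peak_z = numeric()))
    }
    r <- rle(core)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    ki <- which(r$values & r$lengths >= min_dur_s * sig$rate_hz)
    if (length(ki) == 0) {
      return(tibble(tetrode_id = integer(), start = numeric(),
                    end = numeric(), peak_z = numeric()))
    }
    t <- lfp_times(sig)
    below <- which(z <= 0)
    purrr::map_dfr(ki, function(i) {
      s0 <- starts_idx[i]; e0 <- ends_idx[i]
      pre <- below[below < s0]
      post <- below[below > e0]
      s1 <- if (length(pre)) max(pre) + 1L else 1L
      e1 <- if (length(post)) min(post) - 1L else length(z)
      tibble(tetrode_id = sig$tetrode_id, start = t[s1], end = t[e1],
             peak_z = max(z[s0:e0]))
    })
  })
  if (nrow(per_tt) == 0) {
    out <- tibble(tetrode_id = integer(), start = numeric(),
                  end = numeric(), peak_z = numeric())
    class(out) <- c("swr_events", class(out))
    return(out)
  }
  # merge events overlapping across tetrodes
  per_tt <- per_tt[order(per_tt$start), , drop = FALSE]
  merged <- list()
  cur <- per_tt[1, ]
  for (i in seq_len(nrow(per_tt))[-1]) {
    row <- per_tt[i, ]
    if (row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      if (row$peak_z > cur$peak_z) {
        cur$peak_z <- row$peak_z
        cur$tetrode_id <- row$tetrode_id
      }
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- dplyr::bind_rows(merged)
  class(out) <- c("swr_events", class(out))
  out
}

#' SWR rate by task period
#'
#' Counts detected SWR events per included trial inside the odor-sampling
#' window and inside the reward window, and compares the per-trial counts
#' with a signed-rank test.
#'
#' @param events Output of [detect_swr()].
#' @param trials A [trial_table()].
#' @return A list with `per_trial` (tibble: `trial_id`, `odor_count`,
#'   `reward_count`), and `test` (tibble: `statistic`, `p`).
#' @export
swr_rate_by_period <- function(events, trials) {
  inc <- included_trials(trials)
  centers <- (events$start + events$end) / 2
  odor_n <- count_in_windows(centers, cbind(inc$port_in, inc$port_out))
  rw <- cbind(inc$reward_in, inc$reward_out)
  reward_n <- count_in_windows(centers, rw)
  per_trial <- tibble(trial_id = inc$trial_id, odor_count = odor_n,
                      reward_count = reward_n)
  if (all(odor_n == reward_n)) {
    test <- tibble(statistic = 0, p = 1)
  } else {
    wt <- suppressWarnings(
      wilcox.test(reward_n, odor_n, paired = TRUE))
    test <- tibble(statistic = unname(wt$statistic), p = wt$p.value)
  }
  list(per_trial = per_trial, test = test)
}

#' Behavioral summary
#'
#' Performance, hold durations, turn-direction concordance, and its
#' binomial tests. The turn direction at port exit is the sign of the
#' initial lateral (x) head displacement over the 0.5 s following
#' `port_out`; a turn is concordant when it matches the side of the arm
#' ultimately chosen (choice 1 = left = negative x). One-sided binomial
#' tests against 0.5 are run separately for correct and incorrect trials.
#'
#' @param trials A [trial_table()].
#' @param position A [position_trace()].
#' @return A tibble of class `behavior_summary` with `performance`,
#'   `mean_hold_s`, `concordant_correct`, `n_correct`,
#'   `concordant_incorrect`, `n_incorrect`, `binom_p_correct`,
#'   `binom_p_incorrect`, `n_turn_skipped`.
#' @export
behavioral_summary <- function(trials, position) {
  inc <- included_trials(trials)
  if (nrow(inc) < 1) abort("No included trials.")
  perf <- mean(inc$correct)
  hold <- inc$port_out - inc$port_in

  conc <- rep(NA, nrow(inc))
  for (k in seq_len(nrow(inc))) {
    sel <- position$t >= inc$port_out[k] & position$t < inc$port_out[k] + 0.5
    if (sum(sel) < 3) next
    dx <- position$x[sel] - position$x[which(sel)[1]]
    disp <- dx[which.max(abs(dx))]
    if (disp == 0) next
    turn_side <- if (disp < 0) 1L else 2L
    conc[k] <- turn_side == inc$choice[k]
  }
  skipped <- sum(is.na(conc))
  bt <- function(mask) {
    cc <- conc[mask]
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0) return(c(NA_integer_, NA_integer_, NA_real_))
    p <- binom.test(sum(cc), length(cc), p = 0.5,
                    alternative = "greater")$p.value
    c(sum(cc), length(cc), p)
  }
  bc <- bt(inc$correct)
  bi <- bt(!inc$correct)
  out <- tibble(performance = perf, mean_hold_s = mean(hold),
                concordant_correct = bc[1], n_correct = bc[2],
                binom_p_correct = bc[3],
                concordant_incorrect = bi[1], n_incorrect = bi[2],
                binom_p_incorrect = bi[3],
                n_turn_skipped = skipped)
  class(out) <- c("behavior_summary", class(out))
  out
}

#' Sniff rate from a thermocouple trace
#'
#' Band-pass filters the trace at 2-12 Hz and counts oscillation peaks
#' inside each window; the rate is peaks per second. Windows shorter than
#' half a sniff cycle return `NA` and are excluded from the paired
#' comparison.
#'
#' @param thermo Tibble with columns `t`, `value`, sampled at >= 100 Hz.
#' @param windows Matrix/data frame of `(start, end)` windows.
#' @return Numeric vector of per-window rates (Hz).
#' @export
sniff_rate <- function(thermo, windows) {
  windows <- check_windows(windows)
  fs <- 1 / median(diff(thermo$t))
  if (fs < 100) abort("Thermocouple trace must be sampled at >= 100 Hz.")
  bs <- bandpass_zero_phase(thermo$value, c(2, 12), rate_hz = fs)
  x <- bs$filtered
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk_t <- thermo$t[pk]
  vapply(seq_len(nrow(windows)), function(i) {
    dur <- windows[i, 2] - windows[i, 1]
    if (dur <= 0.25) return(NA_real_)
    n <- sum(pk_t >= windows[i, 1] & pk_t < windows[i, 2])
    n / dur
  }, numeric(1))
}

#' Paired pre-odor vs odor sniff-rate comparison
#'
#' @param thermo Thermocouple tibble (`t`, `value`).
#' @param trials A [trial_table()].
#' @return Tibble with `pre_hz`, `odor_hz`, `p` (signed-rank).
#' @export
sniff_rate_contrast <- function(thermo, trials) {
  inc <- included_trials(trials)
  hold <- inc$port_out - inc$port_in
  odor_w <- cbind(inc$port_in, inc$port_out)
  pre_w <- cbind(inc$port_in - hold, inc$port_in)
  r_odor <- sniff_rate(thermo, odor_w)
  r_pre <- sniff_rate(thermo, pre_w)
  ok <- !is.na(r_odor) & !is.na(r_pre)
  wt <- suppressWarnings(wilcox.test(r_odor[ok], r_pre[ok], paired = TRUE))
  tibble(pre_hz = mean(r_pre[ok]), odor_hz = mean(r_odor[ok]),
         p = wt$p.value, n_trials = sum(ok))
}
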