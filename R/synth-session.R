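#' Synthetic session configuration
#'
#' Builds the configuration for the synthetic-session generator. The
#' defaults emulate the statistical structure of the odor-cued T-maze
#' recordings that every downstream analysis assumes: ~100 trials per
#' session at 77% accuracy with a minimum 0.5 s odor-port hold (mean ~0.82
#' s); a respiratory-rhythm (RR) carrier near 7.5 Hz with a beta (20-30 Hz,
#' carrier 25 Hz) component whose amplitude is coupled to RR phase
#' (phase-amplitude coupling) and doubled during odor sampling; pink (1/f)
#' background noise; sharp-wave-ripple bursts at the reward wells; and
#' Poisson units with choice selectivity during the odor period, von Mises
#' spike-phase locking, and Gaussian place fields on the 123 cm linearized
#' outbound route (81 cm stem + 42 cm reward arm).
#'
#' @param n_trials Number of trials (default 100).
#' @param p_correct Probability the choice matches the odor-assigned arm.
#' @param hold_mean_s,hold_sd_s Mean / spread of odor-port hold durations;
#'   holds are 0.5 s plus a gamma-distributed excess.
#' @param premature_frac Fraction of trials terminated before the 0.5 s
#'   minimum hold (excluded downstream).
#' @param rr_hz Respiratory-rhythm frequency (Hz).
#' @param beta_band Beta band limits (Hz); the synthetic carrier sits at the
#'   band center.
#' @param pac_strength Fraction of beta amplitude modulated by RR phase, in
#'   `[0, 1]`.
#' @param odor_beta_gain Beta amplitude multiplier inside odor periods.
#' @param lfp_rate_hz LFP sampling rate (nominally 1500 Hz).
#' @param pos_rate_hz Position sampling rate (30 Hz camera).
#' @param n_pyr,n_int Pyramidal / interneuron counts per region (CA1, PFC).
#' @param kappa_range Range of per-unit von Mises concentrations.
#' @param si_range Range of per-unit choice-selectivity targets.
#' @param choice_persist_s How long choice-selective gain persists past
#'   odor-port exit (transient carry-over onto the track).
#' @param place_frac Fraction of pyramidal units assigned to the
#'   odor-inactive place ensemble (route-preferring spatial field, no
#'   choice tuning); the rest form the odor-active choice ensemble.
#' @param place_peak_gain Multiplicative field peak over the track baseline.
#' @param field_width_cm Gaussian place-field sigma (cm).
#' @param ripple_rate_at_reward SWR event rate at the reward well (Hz).
#' @param ripple_amp Ripple burst amplitude relative to noise scale.
#' @param noise_alpha,noise_scale 1/f^alpha noise exponent and scale.
#' @param run_speed_cms Outbound/return running speed (cm/s).
#' @param sniff_pre_hz,sniff_odor_hz Thermocouple sniff rates before/during
#'   odor sampling.
#' @param with_thermocouple Generate a thermocouple trace?
#' @param track_stem_cm,track_arm_cm T-maze geometry (123 cm route).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_trials = 100,
                         p_correct = 0.77,
                         hold_mean_s = 0.82,
                         hold_sd_s = 0.16,
                         premature_frac = 0.05,
                         rr_hz = 7.5,
                         beta_band = c(20, 30),
                         pac_strength = 0.5,
                         odor_beta_gain = 2,
                         lfp_rate_hz = 1500,
                         pos_rate_hz = 30,
                         n_pyr = 8,
                         n_int = 3,
                         kappa_range = c(0.2, 2),
                         si_range = c(-0.8, 0.8),
                         choice_persist_s = 1.0,
                         place_frac = 0.5,
                         place_peak_gain = 15,
                         field_width_cm = 7,
                         ripple_rate_at_reward = 0.5,
                         ripple_amp = 2.0,
                         noise_alpha = 1,
                         noise_scale = 0.7,
                         run_speed_cms = 30,
                         sniff_pre_hz = 6.2,
                         sniff_odor_hz = 7.1,
                         with_thermocouple = TRUE,
                         track_stem_cm = 81,
                         track_arm_cm = 42) {
  stopifnot(n_trials >= 1, p_correct >= 0, p_correct <= 1,
            beta_band[1] < beta_band[2], pac_strength >= 0, pac_strength <= 1,
            odor_beta_gain >= 1, ripple_rate_at_reward >= 0,
            track_stem_cm + track_arm_cm > 0)
  cfg <- as.list(environment())
  cfg$route_len_cm <- track_stem_cm + track_arm_cm
  cfg$beta_carrier_hz <- mean(beta_band)
  # fixed per-region carrier phase offsets (rad)
  cfg$rr_phase_offset <- c(CA1 = 0, PFC = 0.4, OB = 0.8)
  cfg$beta_phase_offset <- c(CA1 = 0, PFC = 0.5, OB = 1.0)
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic trial table
#'
#' Odor identities are pseudo-random but balanced to within one trial; the
#' choice matches the odor-assigned arm with probability `p_correct`.
#' Premature trials (hold < 0.5 s, no reward-well visit) are generated at
#' `premature_frac` and flagged excluded. Timing columns are filled in by
#' [gen_position()], which lays the trials out on the session clock.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with one row per trial: `trial_id`, `odor`, `choice`,
#'   `correct`, `hold_s`, `premature`.
#' @export
gen_trials <- function(cfg) {
  n <- cfg$n_trials
  odor <- rep(c(1L, 2L), length.out = n)[sample.int(n)]
  correct <- runif(n) < cfg$p_correct
  choice <- ifelse(correct, odor, 3L - odor)
  premature <- runif(n) < cfg$premature_frac
  shape <- 4
  excess_mean <- max(cfg$hold_mean_s - 0.5, 0.05)
  hold <- 0.5 + stats::rgamma(n, shape = shape, scale = excess_mean / shape)
  hold[premature] <- runif(sum(premature), 0.15, 0.45)
  tibble(trial_id = seq_len(n), odor = odor, choice = as.integer(choice),
         correct = correct, hold_s = hold, premature = premature)
}

# T-maze route geometry: linear position s (cm) -> (x, y).
# Stem runs along +y from the odor port at (0, 0); arms extend left
# (choice 1, -x) or right (choice 2, +x) at the junction.
route_xy <- function(s, choice, stem, arm) {
  x <- ifelse(s <= stem, 0, (s - stem) * ifelse(choice == 1, -1, 1))
  y <- pmin(s, stem)
  cbind(x = x, y = y)
}

#' Generate a synthetic position trace
#'
#' Lays trials out sequentially on the session clock and builds the
#' position path: stationary at the odor port through the pre-odor and hold
#' periods, a brief turn toward the chosen side at port exit, an outbound
#' run along the stem and chosen arm at `run_speed_cms`, a pause at the
#' reward well, and a return run. The trial timing columns (`port_in`,
#' `port_out`, `reward_in`, `reward_out`) are attached to the returned
#' trial table.
#'
#' @param cfg A [synth_config()].
#' @param trials Output of [gen_trials()].
#' @return A list with `position` (a [position_trace()] carrying `linear`
#'   and `route` per-sample attributes), `trials` (a [trial_table()] with
#'   absolute times), and `runs` (tibble of true run intervals with routes).
#' @export
gen_position <- function(cfg, trials) {
  fs <- cfg$pos_rate_hz
  dt <- 1 / fs
  run_dur <- cfg$route_len_cm / cfg$run_speed_cms
  pre_s <- 1.5; reward_s <- 2.0; idle_s <- 0.7; turn_lead <- 0.1

  t_list <- list(); x_list <- list(); y_list <- list()
  lin_list <- list(); route_list <- list()
  runs <- list()
  port_in <- port_out <- reward_in <- reward_out <- numeric(nrow(trials))
  t_cur <- 0

  seg <- function(dur, xf, yf, sf, route) {
    nseg <- max(1L, round(dur * fs))
    tt <- t_cur + (seq_len(nseg) - 1) * dt
    u <- (tt - t_cur) / dur
    list(t = tt, x = xf(u), y = yf(u), s = sf(u),
         route = rep(route, nseg))
  }
  push <- function(p) {
    t_list[[length(t_list) + 1]] <<- p$t
    x_list[[length(x_list) + 1]] <<- p$x
    y_list[[length(y_list) + 1]] <<- p$y
    lin_list[[length(lin_list) + 1]] <<- p$s
    route_list[[length(route_list) + 1]] <<- p$route
  }
  jitter_xy <- function(n) rnorm(n, 0, 0.03)

  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    # pre-odor idle + hold at port
    hold <- tr$hold_s
    stillness <- pre_s + hold
    nst <- max(1L, round(stillness * fs))
    tt <- t_cur + (seq_len(nst) - 1) * dt
    push(list(t = tt, x = jitter_xy(nst), y = jitter_xy(nst),
              s = rep(0, nst), route = rep(NA_character_, nst)))
    port_in[k] <- t_cur + pre_s
    port_out[k] <- t_cur + pre_s + hold
    t_cur <- t_cur + stillness

    if (tr$premature) {
      reward_in[k] <- NA; reward_out[k] <- NA
      nid <- round(2.0 * fs)
      tt <- t_cur + (seq_len(nid) - 1) * dt
      push(list(t = tt, x = jitter_xy(nid), y = jitter_xy(nid),
                s = rep(0, nid), route = rep(NA_character_, nid)))
      t_cur <- t_cur + 2.0
      next
    }

    route <- if (tr$choice == 1) "out_left" else "out_right"
    turn_sign <- if (tr$choice == 1) -1 else 1

    # short stationary lead before the run starts
    nld <- max(1L, round(turn_lead * fs))
    tt <- t_cur + (seq_len(nld) - 1) * dt
    push(list(t = tt, x = jitter_xy(nld), y = jitter_xy(nld),
              s = rep(0, nld), route = rep(NA_character_, nld)))
    t_cur <- t_cur + turn_lead

    # outbound run with an initial lateral turn toward the chosen side
    run_start <- t_cur
    nrun <- round(run_dur * fs)
    tt <- t_cur + (seq_len(nrun) - 1) * dt
    s <- cfg$route_len_cm * (tt - t_cur) / run_dur
    xy <- route_xy(s, tr$choice, cfg$track_stem_cm, cfg$track_arm_cm)
    into <- tt - t_cur
    wig <- ifelse(into < 0.5, turn_sign * 4 * sin(pi * into / 0.5), 0)
    push(list(t = tt, x = xy[, "x"] + wig, y = xy[, "y"], s = s,
              route = rep(route, nrun)))
    t_cur <- t_cur + run_dur
    runs[[length(runs) + 1]] <- tibble(
      trial_id = tr$trial_id, start = run_start, end = t_cur,
      route = route, direction = "outbound")

    # reward-well pause
    reward_in[k] <- t_cur
    reward_out[k] <- t_cur + reward_s
    nrw <- round(reward_s * fs)
    tt <- t_cur + (seq_len(nrw) - 1) * dt
    wx <- route_xy(cfg$route_len_cm, tr$choice, cfg$track_stem_cm,
                   cfg$track_arm_cm)
    push(list(t = tt, x = wx[, "x"] + jitter_xy(nrw),
              y = wx[, "y"] + jitter_xy(nrw),
              s = rep(cfg$route_len_cm, nrw), route = rep(NA_character_, nrw)))
    t_cur <- t_cur + reward_s

    # return run
    ret_start <- t_cur
    tt <- t_cur + (seq_len(nrun) - 1) * dt
    s <- cfg$route_len_cm * (1 - (tt - t_cur) / run_dur)
    xy <- route_xy(s, tr$choice, cfg$track_stem_cm, cfg$track_arm_cm)
    push(list(t = tt, x = xy[, "x"], y = xy[, "y"], s = s,
              route = rep(if (tr$choice == 1) "in_left" else "in_right", nrun)))
    t_cur <- t_cur + run_dur
    runs[[length(runs) + 1]] <- tibble(
      trial_id = tr$trial_id, start = ret_start, end = t_cur,
      route = if (tr$choice == 1) "in_left" else "in_right",
      direction = "inbound")

    nid <- round(idle_s * fs)
    tt <- t_cur + (seq_len(nid) - 1) * dt
    push(list(t = tt, x = jitter_xy(nid), y = jitter_xy(nid),
              s = rep(0, nid), route = rep(NA_character_, nid)))
    t_cur <- t_cur + idle_s
  }

  pos <- position_trace(unlist(t_list), unlist(x_list), unlist(y_list))
  attr(pos, "linear") <- unlist(lin_list)
  attr(pos, "route") <- unlist(route_list)
  class(pos) <- c("position_trace", "tbl_df", "tbl", "data.frame")

  tt <- tibble(
    trial_id = trials$trial_id, odor = trials$odor,
    port_in = port_in, port_out = port_out,
    choice = trials$choice, correct = trials$correct,
    reward_in = reward_in, reward_out = reward_out)
  list(position = pos, trials = trial_table(tt),
       runs = dplyr::bind_rows(runs))
}

# Instantaneous carrier phases for a region (closed form; phase 0 at peak).
carrier_phase <- function(t, freq, offset) wrap_pi(2 * pi * freq * t + offset)

#' Generate synthetic LFP traces
#'
#' Per region, the trace is an RR-band carrier plus a beta carrier whose
#' amplitude is (a) modulated by RR phase with depth `pac_strength` and (b)
#' multiplied by `odor_beta_gain` inside odor-sampling windows, plus 1/f
#' noise. Ripple-band (200 Hz, 50-80 ms) bursts are injected at reward
#' wells at `ripple_rate_at_reward` on the CA1 channels.
#'
#' @param cfg A [synth_config()].
#' @param trials A [trial_table()] with absolute times (from
#'   [gen_position()]).
#' @param duration_s Total session duration (s).
#' @return A list with `lfp` (list of [lfp_signal()], one per region plus a
#'   second CA1 tetrode) and `ripples` (tibble of injected ripple times).
#' @export
gen_lfp <- function(cfg, trials, duration_s) {
  fs <- cfg$lfp_rate_hz
  n <- ceiling(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ow <- odor_windows(trials)
  odor_mask <- in_windows(t, ow)

  # ripple events are drawn once and injected into every CA1 channel, as a
  # real SWR appears across tetrodes
  ripples <- tibble(trial_id = integer(), center = numeric(),
                    duration = numeric())
  if (cfg$ripple_rate_at_reward > 0 && fs >= 600) {
    inc <- included_trials(trials)
    rl <- list()
    for (k in seq_len(nrow(inc))) {
      r0 <- inc$reward_in[k]; r1 <- inc$reward_out[k]
      n_ev <- rpois(1, cfg$ripple_rate_at_reward * (r1 - r0))
      if (n_ev == 0) next
      centers <- sort(runif(n_ev, r0 + 0.05, r1 - 0.05))
      rl[[length(rl) + 1]] <- tibble(
        trial_id = inc$trial_id[k], center = centers,
        duration = runif(n_ev, 0.05, 0.08))
    }
    if (length(rl)) ripples <- dplyr::bind_rows(rl)
  }

  make_region <- function(region, tetrode_id, with_ripples = FALSE) {
    th_rr <- 2 * pi * cfg$rr_hz * t + cfg$rr_phase_offset[[region]]
    th_b <- 2 * pi * cfg$beta_carrier_hz * t + cfg$beta_phase_offset[[region]]
    a_beta <- 0.5 * (1 + cfg$pac_strength * cos(th_rr)) *
      ifelse(odor_mask, cfg$odor_beta_gain, 1)
    x <- cos(th_rr) + a_beta * cos(th_b) +
      pink_noise(n, cfg$noise_alpha, cfg$noise_scale)
    if (with_ripples && nrow(ripples) > 0) {
      for (j in seq_len(nrow(ripples))) {
        ct <- ripples$center[j]; dur <- ripples$duration[j]
        idx <- which(t >= ct - dur / 2 & t < ct + dur / 2)
        env <- exp(-0.5 * ((t[idx] - ct) / (dur / 4))^2)
        x[idx] <- x[idx] + cfg$ripple_amp * cfg$noise_scale * env *
          cos(2 * pi * 200 * (t[idx] - ct))
      }
    }
    lfp_signal(region, tetrode_id, fs, x, t0 = 0)
  }

  lfp <- list(
    make_region("CA1", 1L, with_ripples = TRUE),
    make_region("CA1", 2L, with_ripples = TRUE),
    make_region("PFC", 11L),
    make_region("OB", 21L))
  list(lfp = lfp, ripples = ripples)
}

# Bessel I0 ratio used to normalize the von Mises gain.
vm_gain <- function(theta, kappa, mu) {
  if (kappa <= 0) return(rep(1, length(theta)))
  exp(kappa * cos(theta - mu)) / besselI(kappa, 0)
}

#' Generate synthetic spike trains
#'
#' Units are inhomogeneous Poisson processes sampled by thinning. During
#' the odor period (plus a transient `choice_persist_s` carry-over after
#' port exit) pyramidal rate is scaled by `1 + SI` on chosen-side-1 trials
#' and `1 - SI` on chosen-side-2 trials, so the realized selectivity index
#' equals the target; a von Mises gain `exp(kappa cos(theta - mu)) /
#' I0(kappa)` locks spikes to the region's beta or RR phase without
#' changing mean rate. During outbound runs on a unit's preferred route the
#' rate follows a Gaussian place field on linear position. Interneurons
#' (mean rate > 7 Hz, width < 0.3 ms) are phase-locked throughout.
#'
#' @param cfg A [synth_config()].
#' @param trials A [trial_table()] with absolute times.
#' @param posinfo The list returned by [gen_position()].
#' @return A list with `units` (list of [spike_train()]) and `truth`
#'   (tibble of per-unit ground-truth parameters).
#' @export
gen_spikes <- function(cfg, trials, posinfo) {
  pos <- posinfo$position
  runs <- posinfo$runs
  t_end <- max(pos$t)
  inc <- included_trials(trials)

  # per-unit parameter draws; pyramidal cells form two distinct ensembles:
  # odor-active choice-selective units (no spatial field) and odor-inactive
  # place units (route-preferring field, no choice tuning)
  regions <- c("CA1", "PFC")
  specs <- list()
  uid <- 0L
  for (region in regions) {
    n_place <- round(cfg$n_pyr * cfg$place_frac)
    for (j in seq_len(cfg$n_pyr)) {
      uid <- uid + 1L
      is_place <- j <= n_place
      specs[[uid]] <- tibble(
        unit_id = uid, region = region, cell_type = "pyramidal",
        ensemble = if (is_place) "place" else "choice",
        baseline_hz = runif(1, 2.5, 8),
        si_target = if (is_place) 0 else
          runif(1, cfg$si_range[1], cfg$si_range[2]),
        kappa = runif(1, cfg$kappa_range[1], cfg$kappa_range[2]),
        pref_phase = runif(1, -pi, pi),
        lock_band = if (j %% 2 == 1) "beta" else "rr",
        has_field = is_place,
        field_route = sample(c("out_left", "out_right"), 1),
        field_center_cm = runif(1, 12, cfg$route_len_cm - 12),
        # heterogeneous field sizes, ~14-40 cm full width at 25% of peak
        field_width_cm = cfg$field_width_cm * runif(1, 0.6, 1.7),
        spike_width_ms = runif(1, 0.35, 0.6))
    }
    for (j in seq_len(cfg$n_int)) {
      uid <- uid + 1L
      specs[[uid]] <- tibble(
        unit_id = uid, region = region, cell_type = "interneuron",
        ensemble = "interneuron",
        baseline_hz = runif(1, 9, 15),
        si_target = 0,
        kappa = runif(1, cfg$kappa_range[1], cfg$kappa_range[2]),
        pref_phase = runif(1, -pi, pi),
        lock_band = if (j %% 2 == 1) "beta" else "rr",
        has_field = FALSE, field_route = NA_character_,
        field_center_cm = NA_real_, field_width_cm = NA_real_,
        spike_width_ms = runif(1, 0.15, 0.28))
    }
  }
  truth <- dplyr::bind_rows(specs)
  truth$field_center_cm[!truth$has_field] <- NA_real_

  # selective-period windows: odor period plus persistence after exit
  sel_w <- cbind(inc$port_in, inc$port_out + cfg$choice_persist_s)
  sel_choice <- inc$choice
  out_runs <- runs[runs$direction == "outbound", , drop = FALSE]

  lin_t <- pos$t
  lin_s <- attr(pos, "linear")

  units <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    u <- truth[i, ]
    freq <- if (u$lock_band == "beta") cfg$beta_carrier_hz else cfg$rr_hz
    offs <- if (u$lock_band == "beta") cfg$beta_phase_offset[[u$region]] else
      cfg$rr_phase_offset[[u$region]]
    vm_max <- if (u$kappa > 0) exp(u$kappa) / besselI(u$kappa, 0) else 1

    if (u$cell_type == "interneuron") {
      lam_max <- u$baseline_hz * vm_max
      cand <- cumsum(rexp(ceiling(lam_max * t_end * 1.25) + 50,
                          rate = lam_max))
      cand <- cand[cand < t_end]
      theta <- carrier_phase(cand, freq, offs)
      keep <- runif(length(cand)) <
        (u$baseline_hz * vm_gain(theta, u$kappa, u$pref_phase)) / lam_max
      st <- cand[keep]
    } else {
      b_idle <- 0.4
      b_track <- 0.5
      lam_max <- max(u$baseline_hz * (1 + abs(u$si_target)) * vm_max,
                     b_track * (1 + cfg$place_peak_gain), b_idle)
      cand <- cumsum(rexp(ceiling(lam_max * t_end * 1.25) + 50,
                          rate = lam_max))
      cand <- cand[cand < t_end]
      lam <- rep(b_idle, length(cand))

      if (u$ensemble == "choice") {
        # odor + persistence windows: choice gain x phase-locking gain
        iw <- interval_index(cand, sel_w)
        insel <- !is.na(iw)
        if (any(insel)) {
          sgn <- ifelse(sel_choice[iw[insel]] == 1, 1, -1)
          theta <- carrier_phase(cand[insel], freq, offs)
          lam[insel] <- u$baseline_hz * (1 + sgn * u$si_target) *
            vm_gain(theta, u$kappa, u$pref_phase)
        }
        # flat low rate on the track
        rw <- cbind(out_runs$start, out_runs$end)
        onrun <- !is.na(interval_index(cand, rw)) & !insel
        lam[onrun] <- b_track
      } else {
        # place unit: odor-inactive; spatial field on the preferred route
        rw <- cbind(out_runs$start, out_runs$end)
        ir <- interval_index(cand, rw)
        onrun <- !is.na(ir)
        if (any(onrun)) {
          lam_run <- rep(b_track, sum(onrun))
          on_pref <- out_runs$route[ir[onrun]] == u$field_route
          if (any(on_pref)) {
            s_here <- approx(lin_t, lin_s, xout = cand[onrun][on_pref],
                             rule = 2)$y
            bump <- exp(-0.5 * ((s_here - u$field_center_cm) /
                                  u$field_width_cm)^2)
            lam_run[on_pref] <- b_track * (1 + cfg$place_peak_gain * bump)
          }
          lam[onrun] <- lam_run
        }
      }
      keep <- runif(length(cand)) < lam / lam_max
      st <- cand[keep]
    }
    units[[i]] <- spike_train(
      u$unit_id, u$region,
      tetrode_id = if (u$region == "CA1") 1L else 11L,
      spike_times = st,
      mean_rate_hz = length(st) / t_end,
      spike_width_ms = u$spike_width_ms)
  }
  truth$n_spikes <- vapply(units, function(x) length(x$spike_times), integer(1))
  list(units = units, truth = truth)
}

# Index of the half-open interval containing each time (NA if none).
# windows: matrix (start, end), assumed non-overlapping and sorted.
interval_index <- function(t, windows) {
  if (nrow(windows) == 0) return(rep(NA_integer_, length(t)))
  o <- order(windows[, 1])
  windows <- windows[o, , drop = FALSE]
  i <- findInterval(t, windows[, 1])
  inside <- i >= 1 & t < windows[pmax(i, 1), 2]
  out <- rep(NA_integer_, length(t))
  out[inside] <- o[i[inside]]
  out
}

# Thermocouple: oscillation at the instantaneous sniff rate.
gen_thermocouple <- function(cfg, trials, duration_s, fs = 200) {
  n <- ceiling(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f <- rep(cfg$sniff_pre_hz, n)
  f[in_windows(t, odor_windows(trials))] <- cfg$sniff_odor_hz
  phase <- 2 * pi * cumsum(f) / fs
  tibble(t = t, value = cos(phase) + rnorm(n, 0, 0.1))
}

#' Generate a complete synthetic session
#'
#' Runs [gen_trials()], [gen_position()], [gen_lfp()] and [gen_spikes()]
#' under a single seed and assembles a validated [session_record()] plus
#' the ground truth needed for parameter-recovery tests. The same config
#' and seed always produce an identical session.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @return A list with elements `session` (a `session_record`), `truth`
#'   (per-unit ground-truth tibble), `ripples` (injected SWR times),
#'   `runs` (true run intervals), and `config` (the generating config).
#' @export
synth_session <- function(cfg = synth_config(), seed = 1,
                          session_id = sprintf("synth-%03d", seed)) {
  set.seed(child_seed(seed, 1))
  trials0 <- gen_trials(cfg)
  set.seed(child_seed(seed, 2))
  posinfo <- gen_position(cfg, trials0)
  trials <- posinfo$trials
  duration <- max(posinfo$position$t) + 1 / cfg$pos_rate_hz
  set.seed(child_seed(seed, 3))
  lfpinfo <- gen_lfp(cfg, trials, duration)
  set.seed(child_seed(seed, 4))
  spkinfo <- gen_spikes(cfg, trials, posinfo)
  thermo <- NULL
  if (isTRUE(cfg$with_thermocouple)) {
    set.seed(child_seed(seed, 5))
    thermo <- gen_thermocouple(cfg, trials, duration)
  }
  session <- session_record(session_id, lfpinfo$lfp, spkinfo$units, trials,
                            posinfo$position, thermocouple = thermo)
  list(session = session, truth = spkinfo$truth, ripples = lfpinfo$ripples,
       runs = posinfo$runs, config = cfg)
}
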