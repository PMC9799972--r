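#' 2-D occupancy-normalized rate map
#'
#' Bins position into 2 cm square pixels over the run epochs (speed > 3
#' cm/s, odor-sampling and reward windows excluded), divides the spike
#' count per pixel by the unsmoothed occupancy, and smooths the rate
#' quotient with a 2-D Gaussian (sigma = 2 pixels = 4 cm). Pixels with
#' zero occupancy are `NA`.
#'
#' @param unit A [spike_train()].
#' @param position A [position_trace()].
#' @param epochs Run epochs from [run_epochs()].
#' @param trials Optional [trial_table()]; odor and reward windows are
#'   excluded when provided.
#' @param bin_cm Pixel size (cm).
#' @param smooth_sigma_bins Gaussian sigma in pixels.
#' @return A list of class `rate_map_2d` with `rate` (matrix, Hz),
#'   `occupancy` (s), `x_edges`, `y_edges`.
#' @export
occupancy_rate_map <- function(unit, position, epochs, trials = NULL,
                               bin_cm = 2, smooth_sigma_bins = 2) {
  ep <- as.matrix(epochs)
  sel <- in_windows(position$t, ep)
  if (!is.null(trials)) {
    inc <- included_trials(trials)
    excl <- rbind(cbind(inc$port_in, inc$port_out),
                  cbind(inc$reward_in, inc$reward_out))
    excl <- excl[complete.cases(excl), , drop = FALSE]
    sel <- sel & !in_windows(position$t, excl)
  }
  if (!any(sel)) abort("No position samples in the run epochs.")
  px <- position$x[sel]; py <- position$y[sel]; pt <- position$t[sel]
  dt <- median(diff(position$t))
  x_edges <- seq(floor(min(px)), ceiling(max(px)) + bin_cm, by = bin_cm)
  y_edges <- seq(floor(min(py)), ceiling(max(py)) + bin_cm, by = bin_cm)
  xi <- findInterval(px, x_edges, rightmost.closed = TRUE)
  yi <- findInterval(py, y_edges, rightmost.closed = TRUE)
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  occ <- matrix(0, nx, ny)
  for (i in seq_along(xi)) occ[xi[i], yi[i]] <- occ[xi[i], yi[i]] + dt

  st <- unit$spike_times
  st <- st[in_windows(st, ep)]
  if (!is.null(trials) && length(st) > 0) {
    st <- st[!in_windows(st, excl)]
  }
  spk <- matrix(0, nx, ny)
  if (length(st) > 0) {
    sx <- approx(position$t, position$x, xout = st, rule = 2)$y
    sy <- approx(position$t, position$y, xout = st, rule = 2)$y
    sxi <- findInterval(sx, x_edges, rightmost.closed = TRUE)
    syi <- findInterval(sy, y_edges, rightmost.closed = TRUE)
    ok <- sxi >= 1 & sxi <= nx & syi >= 1 & syi <= ny
    for (i in which(ok)) spk[sxi[i], syi[i]] <- spk[sxi[i], syi[i]] + 1
  }
  rate <- spk / occ
  rate[occ == 0] <- NA_real_
  # separable 2-D Gaussian smoothing on the rate quotient, NA-aware
  rate_s <- smooth2d_na(rate, smooth_sigma_bins)
  structure(list(rate = rate_s, rate_raw = rate, occupancy = occ,
                 x_edges = x_edges, y_edges = y_edges,
                 n_spikes = sum(spk)),
            class = "rate_map_2d")
}

# NA-aware separable 2-D Gaussian smoothing (normalized convolution).
smooth2d_na <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- !is.na(m)
  m0 <- m; m0[!w] <- 0
  sm_rows <- function(x) t(apply(x, 1, gauss_smooth, sigma = sigma))
  sm <- sm_rows(t(sm_rows(t(m0))))
  wn <- sm_rows(t(sm_rows(t(w * 1))))
  out <- sm / wn
  out[!w] <- NA_real_
  out
}

#' Linearize run epochs onto T-maze routes
#'
#' Assigns each run epoch a route by its origin and destination (odor
#' port vs left/right reward well) and projects positions to distance
#' along the route (0 at the origin). Runs that neither start nor end
#' near a recognized landmark are dropped with a warning.
#'
#' @param position A [position_trace()].
#' @param epochs Run epochs from [run_epochs()].
#' @param stem_cm,arm_cm Track geometry (default 81 + 42 = 123 cm).
#' @param landmark_tol_cm Radius for landmark matching (cm).
#' @return A tibble with one row per position sample inside a recognized
#'   run: `run_id`, `route` (`out_left`, `out_right`, `in_left`,
#'   `in_right`), `t`, `linear` (cm from the route origin; for inbound
#'   routes the origin is the reward well), plus an attribute `runs`
#'   (per-run tibble: `run_id`, `route`, `start`, `end`).
#' @export
linearize_runs <- function(position, epochs, stem_cm = 81, arm_cm = 42,
                           landmark_tol_cm = 15) {
  route_len <- stem_cm + arm_cm
  port <- c(0, 0)
  well_l <- c(-arm_cm, stem_cm)
  well_r <- c(arm_cm, stem_cm)
  near <- function(x, y, p) sqrt((x - p[1])^2 + (y - p[2])^2) < landmark_tol_cm

  samples <- list(); runsmeta <- list()
  dropped <- 0L
  for (i in seq_len(nrow(epochs))) {
    sel <- position$t >= epochs$start[i] & position$t < epochs$end[i]
    if (sum(sel) < 3) next
    x <- position$x[sel]; y <- position$y[sel]; t <- position$t[sel]
    n <- length(x)
    at_port_s <- near(x[1], y[1], port)
    at_l_e <- near(x[n], y[n], well_l); at_r_e <- near(x[n], y[n], well_r)
    at_l_s <- near(x[1], y[1], well_l); at_r_s <- near(x[1], y[1], well_r)
    at_port_e <- near(x[n], y[n], port)
    route <- if (at_port_s && at_l_e) "out_left"
    else if (at_port_s && at_r_e) "out_right"
    else if (at_l_s && at_port_e) "in_left"
    else if (at_r_s && at_port_e) "in_right"
    else NA_character_
    if (is.na(route)) { dropped <- dropped + 1L; next }
    # distance along the stem + arm polyline (port at y = 0, arms at
    # y = stem_cm): stem progress plus lateral arm progress
    s_along <- pmax(0, pmin(route_len, pmin(pmax(y, 0), stem_cm) + abs(x)))
    if (route %in% c("in_left", "in_right")) s_along <- route_len - s_along
    samples[[length(samples) + 1]] <- tibble(
      run_id = i, route = route, t = t, linear = s_along)
    runsmeta[[length(runsmeta) + 1]] <- tibble(
      run_id = i, route = route, start = epochs$start[i],
      end = epochs$end[i])
  }
  if (dropped > 0) {
    warn(sprintf("%d run(s) dropped: ambiguous route.", dropped))
  }
  out <- dplyr::bind_rows(samples)
  attr(out, "runs") <- dplyr::bind_rows(runsmeta)
  out
}

#' Linearized tuning curve
#'
#' Occupancy-normalized firing rate in 100 bins of `route_len / 100` cm
#' (1.23 cm on the full maze) along one route, Gaussian-smoothed with
#' sigma = 2 bins (4 cm on the 2 cm-scale maps; here 2 bins of the
#' linearized map).
#'
#' @param unit A [spike_train()].
#' @param lin Output of [linearize_runs()] (or a tibble with `t`,
#'   `linear`, `route`, `run_id`).
#' @param route Route label to select.
#' @param route_len Route length (cm).
#' @param n_bins Number of bins (100).
#' @param smooth_sigma_bins Gaussian sigma in bins.
#' @return A list of class `linear_tuning_curve` with `rate` (length
#'   `n_bins`, Hz), `rate_raw`, `occupancy` (s), `bin_centers` (cm),
#'   `route`, `n_runs`.
#' @export
linear_tuning_curve <- function(unit, lin, route, route_len = 123,
                                n_bins = 100, smooth_sigma_bins = 2) {
  seg <- lin[lin$route == route, , drop = FALSE]
  if (nrow(seg) == 0) abort(sprintf("No samples on route %s.", route))
  dt <- median(diff(sort(unique(lin$t))))
  edges <- seq(0, route_len, length.out = n_bins + 1)
  bi <- pmin(n_bins, pmax(1, findInterval(seg$linear, edges,
                                          rightmost.closed = TRUE)))
  occ <- tabulate(bi, nbins = n_bins) * dt

  run_ids <- unique(seg$run_id)
  spk <- numeric(n_bins)
  for (rid in run_ids) {
    rs <- seg[seg$run_id == rid, ]
    st <- unit$spike_times
    st <- st[st >= min(rs$t) & st <= max(rs$t)]
    if (length(st) == 0) next
    s_at <- approx(rs$t, rs$linear, xout = st, rule = 2)$y
    sbi <- pmin(n_bins, pmax(1, findInterval(s_at, edges,
                                             rightmost.closed = TRUE)))
    spk <- spk + tabulate(sbi, nbins = n_bins)
  }
  rate_raw <- ifelse(occ > 0, spk / occ, 0)
  rate <- gauss_smooth(rate_raw, smooth_sigma_bins)
  structure(list(rate = rate, rate_raw = rate_raw, occupancy = occ,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 route = route, n_runs = length(run_ids),
                 n_spikes = sum(spk)),
            class = "linear_tuning_curve")
}

# Flood fill outward from the peak until the rate drops below frac*peak.
flood_fill_bounds <- function(rate, peak_bin, frac = 0.25) {
  thr <- frac * rate[peak_bin]
  lo <- peak_bin
  while (lo > 1 && rate[lo - 1] >= thr) lo <- lo - 1
  hi <- peak_bin
  while (hi < length(rate) && rate[hi + 1] >= thr) hi <- hi + 1
  c(lo, hi)
}

#' Place-field detection on a linearized tuning curve
#'
#' A candidate field requires a peak rate of at least 1 Hz. Field bounds
#' are found by flood fill from the peak bin outward until the rate falls
#' below 25% of the peak. The field is significant if the observed peak
#' is at least 2 SD above the mean of a bootstrap distribution obtained
#' by circularly shifting each run's spikes in time (preserving every
#' run's spike count), and the field covers less than 75% of the route.
#'
#' @param unit A [spike_train()].
#' @param lin Output of [linearize_runs()].
#' @param route Route label.
#' @param n_boot Number of circular-shift bootstraps (default 500); 0 skips
#'   the significance bootstrap (`significant` is then `NA`), useful when
#'   only the field geometry is needed.
#' @param min_runs Minimum traversals of the route.
#' @param route_len,n_bins,smooth_sigma_bins Passed to
#'   [linear_tuning_curve()].
#' @return A tibble of class `place_field` (or `NULL` if no candidate):
#'   `route`, `peak_bin`, `peak_rate_hz`, `bound_lo`, `bound_hi`,
#'   `width_cm`, `sparsity`, `information_bits`, `boot_mean`, `boot_sd`,
#'   `significant`.
#' @export
detect_place_field <- function(unit, lin, route, n_boot = 500, min_runs = 5,
                               route_len = 123, n_bins = 100,
                               smooth_sigma_bins = 2) {
  seg <- lin[lin$route == route, , drop = FALSE]
  n_runs <- length(unique(seg$run_id))
  if (n_runs < min_runs) {
    abort(sprintf("Route %s traversed %d < %d times.", route, n_runs,
                  min_runs))
  }
  tc <- linear_tuning_curve(unit, lin, route, route_len, n_bins,
                            smooth_sigma_bins)
  if (all(tc$rate <= 0)) return(NULL)
  peak_bin <- which.max(tc$rate)      # lowest index on exact ties
  peak <- tc$rate[peak_bin]
  if (peak < 1) return(NULL)
  bounds <- flood_fill_bounds(tc$rate, peak_bin)
  width_bins <- bounds[2] - bounds[1] + 1
  bin_cm <- route_len / n_bins
  fs <- field_stats(tc)

  # circular-shift bootstrap of per-run spike trains
  if (n_boot > 0) {
    boot_peaks <- vapply(seq_len(n_boot), function(b) {
      sh <- shift_unit_spikes(unit, seg)
      tcb <- linear_tuning_curve(sh, lin, route, route_len, n_bins,
                                 smooth_sigma_bins)
      max(tcb$rate)
    }, numeric(1))
    bm <- mean(boot_peaks); bs <- sd(boot_peaks)
    significant <- peak >= bm + 2 * bs &&
      width_bins < 0.75 * n_bins
  } else {
    bm <- NA_real_; bs <- NA_real_; significant <- NA
  }
  out <- tibble(route = route, peak_bin = peak_bin, peak_rate_hz = peak,
                bound_lo = bounds[1], bound_hi = bounds[2],
                width_cm = width_bins * bin_cm, sparsity = fs$sparsity,
                information_bits = fs$information_bits,
                boot_mean = bm, boot_sd = bs, significant = significant,
                n_runs = n_runs)
  class(out) <- c("place_field", class(out))
  out
}

# Circularly shift the unit's spikes within each run's time interval.
shift_unit_spikes <- function(unit, seg) {
  st <- unit$spike_times
  new_st <- st
  for (rid in unique(seg$run_id)) {
    rs <- seg[seg$run_id == rid, ]
    t0 <- min(rs$t); t1 <- max(rs$t)
    idx <- which(st >= t0 & st <= t1)
    if (length(idx) == 0) next
    shift <- runif(1, 0, t1 - t0)
    new_st[idx] <- t0 + (st[idx] - t0 + shift) %% (t1 - t0)
  }
  spike_train(unit$unit_id, unit$region, unit$tetrode_id, sort(new_st),
              unit$mean_rate_hz, unit$spike_width_ms)
}

#' Sparsity and spatial information of a tuning curve
#'
#' Skaggs spatial information per spike, `sum_i p_i (lambda_i /
#' lambda_bar) log2(lambda_i / lambda_bar)`, and sparsity `(sum_i p_i
#' lambda_i)^2 / sum_i p_i lambda_i^2`, with `p_i` the occupancy
#' probability of bin i.
#'
#' @param tc A [linear_tuning_curve()] (or a list with `rate` and
#'   `occupancy`).
#' @return A tibble with `sparsity`, `information_bits`, `peak_rate_hz`,
#'   `mean_rate_hz`; information is `NA` (flagged) when the mean rate is
#'   zero.
#' @export
field_stats <- function(tc) {
  occ <- tc$occupancy
  rate <- tc$rate
  p <- occ / sum(occ)
  lam_bar <- sum(p * rate)
  if (lam_bar <= 0) {
    warn("Mean rate is zero; information undefined.")
    return(tibble(sparsity = NA_real_, information_bits = NA_real_,
                  peak_rate_hz = max(rate), mean_rate_hz = 0))
  }
  ratio <- rate / lam_bar
  info <- sum(p * ratio * log2(pmax(ratio, .Machine$double.xmin)) *
                (rate > 0))
  sparsity <- lam_bar^2 / sum(p * rate^2)
  tibble(sparsity = sparsity, information_bits = info,
         peak_rate_hz = max(rate), mean_rate_hz = lam_bar)
}

#' Trajectory selectivity
#'
#' Pearson correlation between a unit's left- and right-route linearized
#' tuning curves, against a null in which route identity is shuffled
#' across runs; the unit is trajectory-selective when the observed
#' correlation lies below the 5th percentile of the shuffle (i.e. the two
#' spatial patterns are anticorrelated beyond chance). Also reports a
#' trajectory selectivity index from the mean run rates, `(rL - rR) /
#' (rL + rR)`, using run windows that start 0.5 s after odor-port exit
#' once speed exceeds 3 cm/s and end at the goal or when speed stays
#' below 3 cm/s for more than 0.5 s.
#'
#' @param unit A [spike_train()].
#' @param lin Output of [linearize_runs()].
#' @param n_shuffle Number of route-identity shuffles.
#' @param min_runs Minimum traversals per route.
#' @param route_len,n_bins Passed to [linear_tuning_curve()].
#' @return A tibble of class `trajectory_selectivity` with `corr_lr`,
#'   `shuffle_p5`, `selective`, `traj_si`, `n_left`, `n_right`.
#' @export
trajectory_selectivity <- function(unit, lin, n_shuffle = 500, min_runs = 5,
                                   route_len = 123, n_bins = 100) {
  runs <- attr(lin, "runs")
  out_runs <- runs[runs$route %in% c("out_left", "out_right"), ,
                   drop = FALSE]
  nL <- sum(out_runs$route == "out_left")
  nR <- sum(out_runs$route == "out_right")
  if (nL < min_runs || nR < min_runs) {
    abort(sprintf("Both routes need >= %d runs (have %d / %d).",
                  min_runs, nL, nR))
  }
  tcl <- linear_tuning_curve(unit, lin, "out_left", route_len, n_bins)
  tcr <- linear_tuning_curve(unit, lin, "out_right", route_len, n_bins)
  obs <- suppressWarnings(cor(tcl$rate, tcr$rate))
  if (is.na(obs)) obs <- 0

  # shuffle route identity across outbound runs
  null_corr <- vapply(seq_len(n_shuffle), function(s) {
    perm <- sample(out_runs$route)
    lin_s <- lin
    for (i in seq_len(nrow(out_runs))) {
      lin_s$route[lin_s$run_id == out_runs$run_id[i]] <- perm[i]
    }
    a <- linear_tuning_curve(unit, lin_s, "out_left", route_len, n_bins)
    b <- linear_tuning_curve(unit, lin_s, "out_right", route_len, n_bins)
    r <- suppressWarnings(cor(a$rate, b$rate))
    if (is.na(r)) 0 else r
  }, numeric(1))
  p5 <- quantile(null_corr, 0.05, names = FALSE)
  selective <- obs < p5

  # mean run rates per route (whole-run windows from the run metadata)
  run_rate <- function(route) {
    rr <- out_runs[out_runs$route == route, ]
    tot_t <- sum(rr$end - rr$start)
    n <- sum(count_in_windows(unit$spike_times, cbind(rr$start, rr$end)))
    n / tot_t
  }
  rL <- run_rate("out_left"); rR <- run_rate("out_right")
  traj_si <- if (rL + rR > 0) (rL - rR) / (rL + rR) else NA_real_
  out <- tibble(corr_lr = obs, shuffle_p5 = p5, selective = selective,
                traj_si = traj_si, n_left = nL, n_right = nR)
  class(out) <- c("trajectory_selectivity", class(out))
  out
}
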