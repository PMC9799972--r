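test_that("2-D rate map conserves spikes and recovers homogeneous rates", {
  set.seed(60)
  # uniform random walk over a 40x40 cm box at 30 Hz
  n <- 30 * 240
  t <- seq_len(n) / 30
  pos <- position_trace(t, runif(n, 0, 40), runif(n, 0, 40),
                        speed = rep(10, n))
  ep <- tibble::tibble(start = 0, end = max(t) + 1)
  u <- poisson_train(5, max(t), 1)
  m <- occupancy_rate_map(u, pos, ep)
  # conservation: rate_raw * occupancy sums back to the spike count
  tot <- sum(m$rate_raw * m$occupancy, na.rm = TRUE)
  expect_equal(tot, m$n_spikes, tolerance = 0.01 * m$n_spikes)
  # homogeneous 5 Hz within sampling error
  expect_equal(mean(m$rate, na.rm = TRUE), 5, tolerance = 1)

  silent <- spike_train(2, "CA1", 1, numeric(0), 0, 0.5)
  m0 <- occupancy_rate_map(silent, pos, ep)
  expect_true(all(m0$rate == 0 | is.na(m0$rate)))
})

test_that("stationary-period spikes are excluded by the epoch filter", {
  n <- 30 * 100
  t <- seq_len(n) / 30
  pos <- position_trace(t, rep(1, n), rep(1, n), speed = rep(10, n))
  ep <- tibble::tibble(start = 40, end = 60)   # only this window counts
  u <- spike_train(1, "CA1", 1, c(10, 20, 45, 50, 80), 1, 0.5)
  m <- occupancy_rate_map(u, pos, ep)
  expect_equal(m$n_spikes, 2)
})

test_that("linearization assigns routes and the documented bin width", {
  ss <- shared_session()
  s <- ss$session
  ep <- run_epochs(s$position)
  lin <- linearize_runs(s$position, ep)
  runs <- attr(lin, "runs")
  inc <- s$trials[s$trials$included, ]
  # left choices produce out_left outbound runs
  expect_equal(sum(runs$route == "out_left"), sum(inc$choice == 1))
  expect_equal(sum(runs$route == "out_right"), sum(inc$choice == 2))
  # linear position monotone within an outbound run once the initial
  # turn away from the port is over, and spanning the full route
  r1 <- runs$run_id[runs$route %in% c("out_left", "out_right")][1]
  seg <- lin[lin$run_id == r1, ]
  late <- seg[seg$t >= min(seg$t) + 0.7, ]
  expect_true(all(diff(late$linear) >= -0.25))  # jitter at the well edge
  expect_gt(max(seg$linear), 115)
  # an ideal straight run linearizes strictly increasing
  tt <- seq(0, 4, by = 1 / 30)
  ideal <- position_trace(tt, rep(0, length(tt)),
                          pmin(tt * 30, 81) + pmax(tt * 30 - 81, 0) * 0,
                          speed = rep(30, length(tt)))
  ep_i <- tibble::tibble(start = 0, end = max(tt) + 1)
  li <- suppressWarnings(linearize_runs(ideal, ep_i))
  if (nrow(li) > 0) expect_true(all(diff(li$linear) >= -1e-9))
  # 100 bins over 123 cm -> 1.23 cm bins
  u <- s$units[[which(ss$truth$has_field)[1]]]
  tc <- linear_tuning_curve(u, lin, "out_left")
  expect_equal(length(tc$rate), 100)
  expect_equal(diff(tc$bin_centers)[1], 1.23, tolerance = 1e-9)
})

test_that("field stats match closed forms and a brute-force oracle", {
  # uniform rate: information 0, sparsity 1
  tc_u <- list(rate = rep(4, 100), occupancy = rep(0.5, 100))
  fs_u <- field_stats(tc_u)
  expect_equal(fs_u$information_bits, 0, tolerance = 1e-12)
  expect_equal(fs_u$sparsity, 1, tolerance = 1e-12)

  # all rate in one bin, uniform occupancy: info = log2(100), sparsity 0.01
  rate1 <- c(10, rep(0, 99))
  fs_1 <- field_stats(list(rate = rate1, occupancy = rep(1, 100)))
  expect_equal(fs_1$information_bits, log2(100), tolerance = 1e-12)
  expect_equal(fs_1$sparsity, 0.01, tolerance = 1e-12)

  # random curve vs independent direct summation
  set.seed(61)
  rate <- runif(100, 0, 8)
  occ <- runif(100, 0.1, 1)
  p <- occ / sum(occ)
  lam <- sum(p * rate)
  want_info <- sum(p[rate > 0] * (rate[rate > 0] / lam) *
                     log2(rate[rate > 0] / lam))
  want_spars <- lam^2 / sum(p * rate^2)
  got <- field_stats(list(rate = rate, occupancy = occ))
  expect_equal(got$information_bits, want_info, tolerance = 1e-12)
  expect_equal(got$sparsity, want_spars, tolerance = 1e-12)

  expect_warning(field_stats(list(rate = rep(0, 100),
                                  occupancy = rep(1, 100))),
                 "undefined")
})

test_that("flood-fill bounds are contiguous, contain the peak, and shrink
           with the threshold", {
  rate <- 0.2 + 8 * exp(-0.5 * ((1:100 - 50) / 5)^2)
  b25 <- rhythmdecode:::flood_fill_bounds(rate, 50, 0.25)
  expect_true(b25[1] <= 50 && 50 <= b25[2])
  # analytic 25% crossing of a Gaussian: 50 +/- sigma*sqrt(2 ln 4) ~ 8.3 bins
  expect_equal(b25[1], 50 - 9, tolerance = 2)
  expect_equal(b25[2], 50 + 9, tolerance = 2)
  b50 <- rhythmdecode:::flood_fill_bounds(rate, 50, 0.5)
  expect_lte(b25[1], b50[1])
  expect_gte(b25[2], b50[2])
})

test_that("place-field detection applies the 1 Hz and 75% coverage rules", {
  ss <- shared_session()
  s <- ss$session
  ep <- run_epochs(s$position)
  lin <- linearize_runs(s$position, ep)
  i <- which(ss$truth$has_field)[1]
  u <- s$units[[i]]
  pf <- detect_place_field(u, lin, ss$truth$field_route[i], n_boot = 80)
  expect_false(is.null(pf))
  expect_true(pf$significant)
  est_cm <- pf$peak_bin * 1.23 - 0.615
  expect_lt(abs(est_cm - ss$truth$field_center_cm[i]), 6)
  expect_true(pf$bound_lo <= pf$peak_bin && pf$peak_bin <= pf$bound_hi)

  # sub-threshold peak: no field
  weak <- spike_train(99, "CA1", 1,
                      sort(runif(30, 0, max(s$position$t))), 0.2, 0.5)
  expect_true(is.null(detect_place_field(weak, lin, "out_left",
                                         n_boot = 30)) ||
                !detect_place_field(weak, lin, "out_left",
                                    n_boot = 30)$significant)
})

test_that("circular-shift bootstrap preserves each run's spike count", {
  ss <- shared_session()
  s <- ss$session
  ep <- run_epochs(s$position)
  lin <- linearize_runs(s$position, ep)
  i <- which(ss$truth$has_field)[1]
  u <- s$units[[i]]
  seg <- lin[lin$route == ss$truth$field_route[i], ]
  set.seed(62)
  sh <- rhythmdecode:::shift_unit_spikes(u, seg)
  expect_equal(length(sh$spike_times), length(u$spike_times))
  for (rid in unique(seg$run_id)[1:5]) {
    rs <- seg[seg$run_id == rid, ]
    n0 <- sum(u$spike_times >= min(rs$t) & u$spike_times <= max(rs$t))
    n1 <- sum(sh$spike_times >= min(rs$t) & sh$spike_times <= max(rs$t))
    expect_equal(n1, n0)
  }
})

test_that("trajectory selectivity separates route-specific firing", {
  ss <- shared_session()
  s <- ss$session
  ep <- run_epochs(s$position)
  lin <- linearize_runs(s$position, ep)
  i <- which(ss$truth$has_field)[1]
  res <- trajectory_selectivity(s$units[[i]], lin, n_shuffle = 100)
  expect_true(res$selective)
  si_sign <- if (ss$truth$field_route[i] == "out_left") 1 else -1
  expect_gt(si_sign * res$traj_si, 0)

  # identical curves: correlation 1, not selective
  even <- poisson_train(6, max(s$position$t), 50)
  res_e <- trajectory_selectivity(even, lin, n_shuffle = 100)
  expect_gt(res_e$corr_lr, -0.3)
  expect_false(res_e$selective)
})
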