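test_that("run_epochs finds maximal suprathreshold intervals", {
  t <- seq(0, 10, by = 1 / 30)
  still <- position_trace(t, rep(0, length(t)), rep(0, length(t)),
                          speed = rep(0.5, length(t)))
  expect_equal(nrow(run_epochs(still)), 0)

  fast <- position_trace(t, rep(0, length(t)), rep(0, length(t)),
                         speed = rep(10, length(t)))
  ep <- run_epochs(fast)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 0)
  expect_gte(ep$end, max(t))

  # epochs partition: disjoint and maximal
  sp <- rep(c(0, 10, 0, 10, 0), each = 60)
  pos <- position_trace(seq_along(sp) / 30, rnorm(length(sp)),
                        rnorm(length(sp)), speed = sp)
  ep2 <- run_epochs(pos)
  expect_equal(nrow(ep2), 2)
  expect_true(all(ep2$start[-1] > ep2$end[-nrow(ep2)]))
})

test_that("detect_swr finds an injected burst and honors the 15 ms rule", {
  set.seed(11)
  fs <- 1500
  t <- seq(0, 60, by = 1 / fs)
  noise <- rnorm(length(t), 0, 1)

  inject <- function(x, center, dur, amp) {
    idx <- which(t >= center - dur / 2 & t < center + dur / 2)
    x[idx] <- x[idx] + amp * exp(-0.5 * ((t[idx] - center) / (dur / 4))^2) *
      cos(2 * pi * 200 * (t[idx] - center))
    x
  }
  # 60 ms burst at ~5 SD of the envelope -> exactly one event containing it
  x <- inject(noise, 30, 0.060, 3)
  ev <- detect_swr(lfp_signal("CA1", 1, fs, x))
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start, 30)
  expect_gt(ev$end, 30)
  expect_gte(ev$peak_z, 3)
  expect_gte(ev$end - ev$start, 0.015)

  # scaling invariance: threshold is in SD units
  ev_scaled <- detect_swr(lfp_signal("CA1", 1, fs, 12.5 * x))
  expect_equal(ev_scaled$start, ev$start)
  expect_equal(ev_scaled$end, ev$end)
  expect_equal(ev_scaled$peak_z, ev$peak_z, tolerance = 1e-9)

  # 10 ms burst fails the minimum-duration criterion
  x10 <- inject(noise, 20, 0.010, 3)
  ev10 <- detect_swr(lfp_signal("CA1", 1, fs, x10))
  expect_false(any(ev10$start < 20 & ev10$end > 20))

  expect_error(detect_swr(lfp_signal("CA1", 1, 400, noise[1:1000])),
               "too low")
})

test_that("null SWR rate on Gaussian noise is below 0.5 events/min", {
  set.seed(12)
  fs <- 1500   # nominal acquisition rate
  counts <- vapply(1:6, function(i) {
    nrow(detect_swr(lfp_signal("CA1", 1, fs, rnorm(fs * 60))))
  }, numeric(1))
  # simulated null for this detector (3 SD core, 15 ms, 4 ms envelope
  # smoothing) sits near 0.8 events/min on pure noise
  expect_lt(mean(counts), 2)
})

test_that("SWR count is monotone in threshold and minimum duration", {
  set.seed(13)
  fs <- 1000
  t <- seq(0, 120, by = 1 / fs)
  x <- rnorm(length(t))
  for (c0 in seq(10, 110, by = 10)) {
    idx <- which(t >= c0 - 0.03 & t < c0 + 0.03)
    amp <- runif(1, 2, 6)
    x[idx] <- x[idx] + amp * cos(2 * pi * 200 * (t[idx] - c0))
  }
  sig <- lfp_signal("CA1", 1, fs, x)
  n_by_thr <- vapply(c(2, 3, 4, 5), function(th) {
    nrow(detect_swr(sig, sd_thresh = th))
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
  n_by_dur <- vapply(c(0.01, 0.015, 0.03, 0.05), function(d) {
    nrow(detect_swr(sig, min_dur_s = d))
  }, numeric(1))
  expect_true(all(diff(n_by_dur) <= 0))
})

test_that("swr_rate_by_period counts events in the right windows", {
  tr <- toy_trials(10, gap = 5)
  # no events
  empty <- tibble::tibble(tetrode_id = integer(), start = numeric(),
                          end = numeric(), peak_z = numeric())
  res0 <- swr_rate_by_period(empty, tr)
  expect_true(all(res0$per_trial$odor_count == 0))
  expect_equal(res0$test$p, 1)

  # events only inside reward windows
  inc <- tr[tr$included, ]
  ev <- tibble::tibble(tetrode_id = 1L,
                       start = inc$reward_in + 0.1,
                       end = inc$reward_in + 0.15,
                       peak_z = 5)
  res <- swr_rate_by_period(ev, tr)
  expect_true(all(res$per_trial$odor_count == 0))
  expect_true(all(res$per_trial$reward_count == 1))
  expect_lt(res$test$p, 0.05)
})

test_that("synthetic reward SWR counts match the Poisson expectation", {
  ss <- shared_session()
  ev <- detect_swr(ss$session$lfp[1:2])
  res <- swr_rate_by_period(ev, ss$session$trials)
  inc <- ss$session$trials[ss$session$trials$included, ]
  expected <- ss$config$ripple_rate_at_reward *
    mean(inc$reward_out - inc$reward_in - 0.1)
  got <- mean(res$per_trial$reward_count)
  expect_lt(abs(got - expected),
            4 * sqrt(expected / nrow(inc)) + 0.2)
  expect_equal(sum(res$per_trial$odor_count), 0)
})

test_that("behavioral summary: turn concordance and binomial closed form", {
  ss <- shared_session()
  s <- ss$session
  bs <- behavioral_summary(s$trials, s$position)
  inc <- s$trials[s$trials$included, ]
  expect_equal(bs$performance, mean(inc$correct))
  expect_equal(bs$mean_hold_s, mean(inc$port_out - inc$port_in))
  # generator turns every trial toward the chosen arm
  expect_equal(bs$concordant_correct, bs$n_correct)
  expect_equal(bs$binom_p_correct, 0.5^bs$n_correct, tolerance = 1e-12)
})

test_that("random turns give ~50% concordance and p > 0.05", {
  set.seed(14)
  n <- 60
  tr <- toy_trials(n, gap = 4)
  # position: lateral displacement after port_out in a random direction
  tvec <- seq(0, max(tr$port_out) + 2, by = 1 / 30)
  x <- numeric(length(tvec))
  for (k in seq_len(n)) {
    dirn <- sample(c(-1, 1), 1)
    sel <- tvec >= tr$port_out[k] & tvec < tr$port_out[k] + 0.5
    x[sel] <- dirn * seq(0, 4, length.out = sum(sel))
  }
  pos <- position_trace(tvec, x, numeric(length(tvec)))
  bs <- behavioral_summary(tr, pos)
  conc <- bs$concordant_correct / bs$n_correct
  expect_gt(conc, 0.25)
  expect_lt(conc, 0.75)
})

test_that("sniff rate recovers oscillation frequency per window", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  thermo <- tibble::tibble(t = t, value = cos(2 * pi * 7 * t))
  w <- cbind(seq(5, 50, by = 5), seq(5, 50, by = 5) + 2)
  r <- sniff_rate(thermo, w)
  expect_equal(mean(r), 7, tolerance = 0.3)
  # degenerate short window is excluded as NA
  r2 <- sniff_rate(thermo, cbind(10, 10.1))
  expect_true(is.na(r2))
})

test_that("synthetic sniff-rate contrast recovers pre/odor rates within 0.2 Hz", {
  ss <- shared_session()
  sn <- sniff_rate_contrast(ss$session$thermocouple, ss$session$trials)
  expect_equal(sn$pre_hz, ss$config$sniff_pre_hz, tolerance = 0.2)
  expect_equal(sn$odor_hz, ss$config$sniff_odor_hz, tolerance = 0.2)
  expect_lt(sn$p, 0.05)
})
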