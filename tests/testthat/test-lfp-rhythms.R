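test_that("band filter passes an in-band tone and rejects out-of-band", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  x25 <- sin(2 * pi * 25 * t)
  bs <- bandpass_zero_phase(x25, c(20, 30), rate_hz = fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_equal(mean(bs$envelope[mid]), 1, tolerance = 0.02)
  # phase = 0 at signal peaks
  peaks <- which(diff(sign(diff(x25))) == -2) + 1
  peaks <- peaks[peaks > min(mid) & peaks < max(mid)]
  expect_lt(max(abs(bs$phase[peaks])), 0.05)

  x50 <- sin(2 * pi * 50 * t)
  bs50 <- bandpass_zero_phase(x50, c(20, 30), rate_hz = fs)
  expect_lt(mean(bs50$envelope[mid]), 0.05)

  expect_error(bandpass_zero_phase(x25, c(100, 300), rate_hz = fs),
               "Nyquist")
})

test_that("forward-backward filtering is zero phase (impulse symmetry)", {
  fs <- 500
  x <- numeric(2001); x[1001] <- 1
  bs <- bandpass_zero_phase(x, c(20, 30), rate_hz = fs)
  h <- bs$filtered
  left <- h[1001 - (1:300)]
  right <- h[1001 + (1:300)]
  expect_equal(left, right, tolerance = 1e-6)
})

test_that("band phase advances 2*pi per carrier cycle on a pure tone", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  bs <- bandpass_zero_phase(cos(2 * pi * 25 * t), c(20, 30), rate_hz = fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  ph <- rhythmdecode:::unwrap_phase(bs$phase[mid])
  slope <- coef(lm(ph ~ t[mid]))[2]
  expect_equal(unname(slope), 2 * pi * 25, tolerance = 0.01)
})

test_that("narrow RR band filtering is numerically stable at 1500 Hz", {
  fs <- 1500
  t <- seq(0, 30, by = 1 / fs)
  x <- cos(2 * pi * 7.5 * t) + rnorm(length(t), 0, 0.5)
  bs <- bandpass_zero_phase(x, c(7, 8), rate_hz = fs)
  expect_true(all(is.finite(bs$filtered)))
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_equal(mean(bs$envelope[mid]), 1, tolerance = 0.1)
})

test_that("multitaper spectrum of white noise is flat within sampling bands", {
  set.seed(5)
  fs <- 500
  sig <- lfp_signal("CA1", 1, fs, rnorm(fs * 120))
  events <- seq(5, 110, by = 2)
  sp <- multitaper_spectrogram(sig, events, pre_s = 0.5, post_s = 0.5,
                               zscore = FALSE, fmax = 200)
  m <- rowMeans(sp$values)
  # each frequency row averages K tapers x n_events x n_times estimates;
  # relative spread around the common mean must be small
  expect_lt(sd(m[-1]) / mean(m[-1]), 0.1)

  # z-scored output has ~zero mean per frequency row
  spz <- multitaper_spectrogram(sig, events, pre_s = 0.5, post_s = 0.5,
                                zscore = TRUE, fmax = 200)
  expect_lt(max(abs(rowMeans(spz$values))), 1e-10)
})

test_that("coherence is 1 for identical signals and ~1/K for independent noise", {
  set.seed(6)
  fs <- 500
  x <- rnorm(fs * 120)
  a <- lfp_signal("CA1", 1, fs, x)
  b <- lfp_signal("PFC", 11, fs, x)
  events <- seq(5, 110, by = 2)
  coh <- multitaper_coherogram(a, b, events, pre_s = 0.5, post_s = 0.5,
                               fmax = 100)
  expect_true(all(coh$values > 0.999))

  c2 <- lfp_signal("PFC", 11, fs, rnorm(fs * 120))
  coh0 <- multitaper_coherogram(a, c2, events, pre_s = 0.5, post_s = 0.5,
                                fmax = 100)
  # bias floor ~ 1/(K * n_events) per cell after averaging across events;
  # with K = 5 tapers and 53 events the mean is far below 1/K and above 0
  expect_lt(mean(coh0$values), 1 / 5)
  expect_gt(mean(coh0$values), 0)

  # symmetry in the arguments and amplitude-scaling invariance
  coh_ba <- multitaper_coherogram(c2, a, events, pre_s = 0.5, post_s = 0.5,
                                  fmax = 100)
  expect_equal(coh0$values, coh_ba$values, tolerance = 1e-10)
  a_scaled <- lfp_signal("CA1", 1, fs, 7.3 * x)
  coh_s <- multitaper_coherogram(a_scaled, c2, events, pre_s = 0.5,
                                 post_s = 0.5, fmax = 100)
  expect_equal(coh0$values, coh_s$values, tolerance = 1e-9)
})

test_that("shared narrowband component gives in-band coherence only", {
  set.seed(7)
  fs <- 500
  t <- seq(0, 120, by = 1 / fs)
  shared <- cos(2 * pi * 25 * t)
  a <- lfp_signal("CA1", 1, fs, shared + rnorm(length(t)))
  b <- lfp_signal("PFC", 11, fs, shared + rnorm(length(t)))
  events <- seq(5, 110, by = 2)
  coh <- multitaper_coherogram(a, b, events, pre_s = 0.5, post_s = 0.5,
                               fmax = 100)
  inband <- coh$freqs >= 20 & coh$freqs <= 30
  outband <- coh$freqs >= 50 & coh$freqs <= 90
  expect_gt(mean(coh$values[inband, ]), 5 * mean(coh$values[outband, ]))
})

test_that("condition_contrast handles degenerate and one-sided cases", {
  df <- tibble::tibble(session = 1:6, a = c(1, 2, 3, 4, 5, 6),
                       b = c(1, 2, 3, 4, 5, 6))
  res <- condition_contrast(df)
  expect_equal(res$p, 1)
  expect_true(all(attr(res, "deltas") == 0))

  df2 <- df
  df2$b <- df2$a + 0.5
  res2 <- condition_contrast(df2, alternative = "greater")
  # all signs agree: p at/below the minimal exact one-sided level for n = 6
  # (1/64; the tie-corrected normal approximation can fall slightly under)
  expect_lte(res2$p, 1 / 32)
  expect_lt(abs(res2$p - 1 / 64), 0.01)

  df3 <- df
  df3$b[2] <- NA
  expect_warning(res3 <- condition_contrast(df3), "dropped")
  expect_equal(res3$n_sessions, 5)
})

test_that("bootstrap down-sampling test behaves at its edges", {
  set.seed(8)
  odor <- rnorm(200, 5)
  air <- rnorm(20, 5)
  res <- bootstrap_downsample_test(odor, air)
  expect_gte(res$p, 0)

  # air entirely below odor: no bootstrap mean can be that low
  res2 <- bootstrap_downsample_test(runif(100, 10, 11), runif(10, 0, 1))
  expect_equal(res2$p, 0)
  expect_match(res2$p_label, "< 0.001")

  # identical values: p ~ 0.5 by symmetry (ties count as <=)
  res3 <- bootstrap_downsample_test(rep(2, 30), rep(2, 30))
  expect_equal(res3$p, 1)   # all resample means equal the air mean
  expect_error(bootstrap_downsample_test(1:3, 1:5), "numerous")
  expect_warning(bootstrap_downsample_test(rnorm(20), rnorm(5), n_boot = 50),
                 "unreliable")
})

test_that("bootstrap p is calibrated under the null", {
  set.seed(9)
  p <- vapply(1:200, function(i) {
    bootstrap_downsample_test(rnorm(60), rnorm(12), n_boot = 200)$p
  }, numeric(1))
  expect_gt(mean(p >= 0.05), 0.85)
})

test_that("cross-region phase offset recovers a known delay", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  a <- bandpass_zero_phase(cos(2 * pi * 25 * t), c(20, 30), rate_hz = fs)
  b <- bandpass_zero_phase(cos(2 * pi * 25 * (t - 0.01)), c(20, 30),
                           rate_hz = fs)
  w <- cbind(5, 15)
  off <- cross_region_phase_offset(a, b, w)
  # 10 ms at 25 Hz = pi/2; A leads B
  expect_equal(off$mean_offset, pi / 2, tolerance = 0.02)
  expect_gt(off$resultant, 0.99)

  same <- cross_region_phase_offset(a, a, w)
  expect_equal(same$mean_offset, 0, tolerance = 1e-9)
  expect_equal(same$resultant, 1, tolerance = 1e-9)

  set.seed(10)
  n1 <- bandpass_zero_phase(rnorm(length(t)), c(20, 30), rate_hz = fs)
  n2 <- bandpass_zero_phase(rnorm(length(t)), c(20, 30), rate_hz = fs)
  ind <- cross_region_phase_offset(n1, n2, w)
  expect_lt(ind$resultant, 0.25)

  expect_error(cross_region_phase_offset(a, b, cbind(numeric(0), numeric(0))),
               "empty")
})
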