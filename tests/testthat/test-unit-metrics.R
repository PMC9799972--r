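test_that("unit classification applies conjunctive interneuron criteria", {
  tr <- toy_trials(10, gap = 4)
  ep <- tibble::tibble(start = 0, end = 50)
  mk <- function(rate, width, n_spk = 150) {
    spike_train(1, "CA1", 1, sort(runif(n_spk, 0, 45)), rate, width)
  }
  set.seed(30)
  expect_equal(classify_units(list(mk(10, 0.2)), ep, tr)$cell_type,
               "interneuron")
  expect_equal(classify_units(list(mk(10, 0.4)), ep, tr)$cell_type,
               "pyramidal")   # criteria are conjunctive
  expect_equal(classify_units(list(mk(5, 0.2)), ep, tr)$cell_type,
               "pyramidal")
  expect_true(is.na(classify_units(list(mk(10, NA)), ep, tr)$cell_type))

  # 99 run-epoch spikes -> not active (boundary)
  u99 <- spike_train(1, "CA1", 1, sort(runif(99, 0, 45)), 2, 0.5)
  expect_false(classify_units(list(u99), ep, tr)$active)
  u100 <- spike_train(1, "CA1", 1, sort(runif(100, 0, 45)), 2, 0.5)
  expect_true(classify_units(list(u100), ep, tr)$active)
})

test_that("task responsiveness flags rate changes and their direction", {
  set.seed(31)
  tr <- toy_trials(24, hold = 0.8, gap = 4)
  inc <- tr[tr$included, ]
  # rate doubles post-odor on every trial
  st <- c()
  for (k in seq_len(nrow(inc))) {
    st <- c(st, runif(4, inc$port_in[k] - 0.8, inc$port_in[k]),
            runif(8, inc$port_in[k], inc$port_out[k]))
  }
  u <- spike_train(1, "CA1", 1, sort(st), 3, 0.5)
  res <- task_responsiveness(u, tr)
  expect_true(res$responsive)
  expect_equal(res$dir_odor1, 1)
  expect_equal(res$dir_odor2, 1)

  # identical pre/post rates: not responsive
  st2 <- c()
  for (k in seq_len(nrow(inc))) {
    st2 <- c(st2, inc$port_in[k] + c(-0.6, -0.3, 0.2, 0.5))
  }
  res2 <- task_responsiveness(spike_train(1, "CA1", 1, sort(st2), 3, 0.5), tr)
  expect_false(res2$responsive)
})

test_that("a simulated 30% rate increase is detected in most runs", {
  set.seed(32)
  hits <- vapply(1:40, function(i) {
    tr <- toy_trials(100, hold = 1, gap = 4)   # 50 trials per odor
    inc <- tr[tr$included, ]
    st <- c()
    for (k in seq_len(nrow(inc))) {
      st <- c(st, runif(rpois(1, 10), inc$port_in[k] - 1, inc$port_in[k]),
              runif(rpois(1, 13), inc$port_in[k], inc$port_out[k]))
    }
    task_responsiveness(spike_train(1, "CA1", 1, sort(st), 5, 0.5),
                        tr)$responsive
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("selectivity index follows its closed-form arithmetic", {
  set.seed(33)
  tr <- toy_trials(40, hold = 1, gap = 4)
  inc <- tr[tr$included & tr$correct, ]
  mk_with_rates <- function(r1, r2) {
    st <- c()
    for (k in seq_len(nrow(inc))) {
      r <- if (inc$odor[k] == 1) r1 else r2
      n <- round(r * (inc$port_out[k] - inc$port_in[k]))
      if (n > 0) st <- c(st, seq(inc$port_in[k], inc$port_out[k] - 1e-4,
                                 length.out = n))
    }
    spike_train(1, "CA1", 1, sort(st), 3, 0.5)
  }
  expect_equal(choice_selectivity(mk_with_rates(10, 0), tr, 50)$si, 1)
  expect_equal(choice_selectivity(mk_with_rates(6, 6), tr, 50)$si, 0,
               tolerance = 1e-9)
  expect_equal(choice_selectivity(mk_with_rates(6, 2), tr, 50)$si, 0.5,
               tolerance = 1e-9)
})

test_that("SI antisymmetry: swapping odor labels negates SI exactly", {
  ss <- shared_session()
  s <- ss$session
  u <- s$units[[which(ss$truth$ensemble == "choice")[1]]]
  res <- choice_selectivity(u, s$trials, n_shuffle = 10)
  swapped <- s$trials
  swapped$odor <- 3L - swapped$odor
  swapped$correct <- swapped$choice == swapped$odor
  # keep the same trial set: flip choices too so correct trials align
  swapped2 <- s$trials
  swapped2$odor <- 3L - swapped2$odor
  swapped2$choice <- 3L - swapped2$choice
  res2 <- choice_selectivity(u, swapped2, n_shuffle = 10)
  expect_equal(res2$si, -res$si, tolerance = 1e-12)
})

test_that("selectivity shuffle null is centered near zero", {
  ss <- shared_session()
  s <- ss$session
  units <- s$units[ss$truth$ensemble == "choice"]
  res <- dplyr::bind_rows(
    lapply(units, choice_selectivity, trials = s$trials, n_shuffle = 300))
  expect_lt(max(abs(res$null_mean)), 0.12)
})

test_that("correct/incorrect SI anticorrelate for choice-following units", {
  ss <- shared_session()
  s <- ss$session
  units <- s$units[ss$truth$ensemble == "choice"]
  res <- dplyr::bind_rows(
    lapply(units, choice_selectivity, trials = s$trials, n_shuffle = 200))
  sc <- selectivity_correlation(res, selective_only = FALSE)
  expect_lt(sc$rho, 0)

  # exact anticorrelation gives rho = -1
  fake <- tibble::tibble(si = seq(-0.8, 0.8, length.out = 8),
                         si_incorrect = -seq(-0.8, 0.8, length.out = 8),
                         selective = TRUE)
  expect_equal(selectivity_correlation(fake)$rho, -1)
})

test_that("cross-correlogram peaks at the construction lag", {
  set.seed(34)
  a <- sort(runif(1500, 0, 150))
  ua <- spike_train(1, "CA1", 1, a, 10, 0.5)
  # identical trains: peak at lag 0
  same <- jitter_corrected_ccg(ua, spike_train(2, "PFC", 11, a, 10, 0.5),
                               n_jitter = 150)
  expect_true(same$significant)
  expect_lt(abs(same$peak_lag_ms), 2.5)

  # B = A + 10 ms: peak at +10 ms (CA1 leads); brute-force check on raw
  ub <- spike_train(2, "PFC", 11, sort(a + 0.010), 10, 0.5)
  shifted <- jitter_corrected_ccg(ua, ub, n_jitter = 150)
  expect_true(shifted$significant)
  expect_lt(abs(shifted$peak_lag_ms - 10), 2.6)
  lags <- as.vector(outer(a, a + 0.010, FUN = function(x, y) y - x))
  lags <- lags[abs(lags) <= 0.15]
  brute <- as.integer(table(cut(lags, seq(-0.15, 0.15, by = 0.0025),
                                right = FALSE)))
  expect_equal(shifted$raw, brute)
})

test_that("jitter preserves spike count and far-lag z is ~standard normal", {
  set.seed(35)
  a <- sort(runif(800, 0, 100))
  b <- sort(runif(800, 0, 100))
  res <- jitter_corrected_ccg(spike_train(1, "CA1", 1, a, 8, 0.5),
                              spike_train(2, "PFC", 11, b, 8, 0.5),
                              n_jitter = 300)
  expect_false(res$significant)
  v <- var(res$z[abs(res$lags_ms) > 100], na.rm = TRUE)
  expect_gt(v, 0.6)
  expect_lt(v, 1.5)
  expect_error(
    jitter_corrected_ccg(spike_train(1, "CA1", 1, numeric(0)),
                         spike_train(2, "PFC", 11, b)),
    "at least one spike")
})
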