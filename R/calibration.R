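#' False-positive calibration suites
#'
#' Each `calibrate_*()` function simulates data with no effect, applies the
#' corresponding test at nominal alpha = 0.05, and returns the fraction of
#' runs declared significant. A well-calibrated test shows a false-positive
#' rate near 0.05. The simulated problems are deliberately small so that
#' hundreds of seeded runs complete in minutes; the methods vignette states
#' the sizes.
#'
#' @param n_runs Number of seeded simulation runs.
#' @param seed Base seed; run `i` uses a seed derived from it.
#' @param alpha Nominal level.
#' @name calibration
NULL

#' @describeIn calibration PAC trial-shuffle test on uncoupled
#'   phase/amplitude series (10 trials of 0.8 s at 250 Hz per run; 199
#'   shuffles, so the +1-corrected permutation p can attain a level of
#'   0.045 rather than 0.04 at 99 shuffles).
#' @export
calibrate_pac <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  fs <- 250
  tseg <- seq(1 / fs, 0.8, by = 1 / fs)
  hits <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 1000 + i))
    n_tr <- 10
    ph <- c(); am <- c()
    for (k in seq_len(n_tr)) {
      ph <- c(ph, 2 * pi * 7.5 * tseg + runif(1, 0, 2 * pi))
      am <- c(am, 1 + 0.3 * abs(rnorm(length(tseg))))   # independent of phase
    }
    w <- cbind((seq_len(n_tr) - 1) * 0.8, seq_len(n_tr) * 0.8)
    bs_ph <- structure(list(band = c(7, 8), filtered = cos(ph),
                            amplitude = am, phase = wrap_pi(ph),
                            envelope = am, rate_hz = fs, t0 = 0),
                       class = "band_signal")
    suppressWarnings(
      pac_null(bs_ph, bs_ph, w, n_shuffle = 199)$p < alpha)
  }, logical(1))
  mean(hits)
}

#' @describeIn calibration SI permutation test on units with no choice
#'   tuning (40 trials, Poisson 8 Hz both odors, 199 shuffles).
#' @export
calibrate_si <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  hits <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 2000 + i))
    n <- 40
    odor <- rep(c(1L, 2L), n / 2)
    port_in <- 2 * (seq_len(n) - 1)
    tr <- trial_table(tibble(
      trial_id = seq_len(n), odor = odor, port_in = port_in,
      port_out = port_in + 0.8, choice = odor, correct = TRUE,
      reward_in = port_in + 1.2, reward_out = port_in + 1.5))
    st <- sort(unlist(lapply(port_in, function(p0) {
      p0 + runif(rpois(1, 8 * 0.8), 0, 0.8)
    })))
    u <- spike_train(1, "CA1", 1, st, 8, 0.5)
    choice_selectivity(u, tr, n_shuffle = 199)$p_perm < alpha
  }, logical(1))
  mean(hits)
}

#' @describeIn calibration Jitter-CCG global significance on independent
#'   Poisson trains (5 Hz, 60 s, 100 surrogates).
#' @export
calibrate_ccg <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  hits <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 3000 + i))
    a <- spike_train(1, "CA1", 1, sort(runif(300, 0, 60)), 5, 0.5)
    b <- spike_train(2, "PFC", 11, sort(runif(300, 0, 60)), 5, 0.5)
    jitter_corrected_ccg(a, b, n_jitter = 100, alpha = alpha)$significant
  }, logical(1))
  mean(hits)
}

#' @describeIn calibration Rayleigh test on uniform phases (n = 150 spikes
#'   per run).
#' @export
calibrate_rayleigh <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  hits <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 4000 + i))
    rayleigh_test(runif(150, -pi, pi))$p < alpha
  }, logical(1))
  mean(hits)
}

#' @describeIn calibration GLM choice prediction on label-independent
#'   counts (40 trials, 8 units, final 1 s window, 20 shuffled-null
#'   repetitions per run).
#' @export
calibrate_glm <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  hits <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 5000 + i))
    n_tr <- 40; n_u <- 8
    labels <- sample(rep(c(1L, 2L), n_tr / 2))
    vals <- array(rpois(n_tr * 10 * n_u, 5), c(n_tr, 10, n_u)) / 0.1
    rm_ <- structure(list(values = vals, units = seq_len(n_u),
                          trial_id = seq_len(n_tr), choice = labels,
                          correct = rep(TRUE, n_tr),
                          bin_edges = seq(0, 1, by = 0.1),
                          alignment = "odor_on"),
                     class = "rate_matrix")
    res <- glm_choice_prediction(rm_, n_shuffle = 20, windows_s = 1.0)
    res$p < alpha
  }, logical(1))
  mean(hits)
}

#' @describeIn calibration PCA trajectory discrimination on exchangeable
#'   data: returns the mean per-bin exceedance rate of the pointwise 95%
#'   null band (nominally 0.05; the band is pointwise, so any-bin detection
#'   runs higher, which the methods vignette documents).
#' @export
calibrate_pca <- function(n_runs = 200, seed = 1, alpha = 0.05) {
  exc <- vapply(seq_len(n_runs), function(i) {
    set.seed(child_seed(seed, 6000 + i))
    n_tr <- 40; n_u <- 8
    vals <- array(rnorm(n_tr * 10 * n_u, 5, 1), c(n_tr, 10, n_u))
    rm_ <- structure(list(values = vals, units = seq_len(n_u),
                          trial_id = seq_len(n_tr),
                          choice = rep(c(1L, 2L), n_tr / 2),
                          correct = rep(TRUE, n_tr),
                          bin_edges = seq(0, 1, by = 0.1),
                          alignment = "odor_on"),
                     class = "rate_matrix")
    res <- pca_discrimination(rm_, n_shuffle = 100)
    mean(res$dist > res$null_ci95)
  }, numeric(1))
  mean(exc)
}
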