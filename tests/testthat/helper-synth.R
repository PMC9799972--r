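# Shared fixtures, built once per test run.

# Small synthetic session reused across module tests: 30 trials, reduced
# LFP rate (ripple band still resolvable needs >= 600 Hz; use 1000).
shared_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_trials = 30, lfp_rate_hz = 1000, n_pyr = 6,
                          n_int = 2, pac_strength = 0.6)
      cache <<- synth_session(cfg, seed = 42)
    }
    cache
  }
})

# Minimal hand-built trial table: n trials, alternating odors, all correct
# unless flips[i], unit hold and spacing.
toy_trials <- function(n, hold = 0.8, gap = 2, flips = rep(FALSE, n),
                       premature = rep(FALSE, n)) {
  odor <- rep(c(1L, 2L), length.out = n)
  choice <- ifelse(flips, 3L - odor, odor)
  port_in <- gap * (seq_len(n) - 1) + 0.5
  hold_v <- ifelse(premature, 0.3, hold)
  tibble::tibble(
    trial_id = seq_len(n), odor = odor, port_in = port_in,
    port_out = port_in + hold_v, choice = choice, correct = choice == odor,
    reward_in = ifelse(premature, NA_real_, port_in + hold_v + 0.5),
    reward_out = ifelse(premature, NA_real_, port_in + hold_v + 1.0)) |>
    trial_table()
}

# Homogeneous Poisson spikes over [0, t_end).
poisson_train <- function(rate, t_end, unit_id = 1L, region = "CA1",
                          width = 0.5) {
  n <- stats::rpois(1, rate * t_end)
  spike_train(unit_id, region, 1L, sort(stats::runif(n, 0, t_end)),
              mean_rate_hz = rate, spike_width_ms = width)
}

# Fake band_signal carrying given phase/amplitude series (for PAC and
# phase tests that do not need a real filter run).
fake_band_signal <- function(phase, amplitude, rate_hz, band = c(7, 8),
                             t0 = 0) {
  structure(list(band = band, filtered = amplitude * cos(phase),
                 amplitude = amplitude, phase = rhythmdecode:::wrap_pi(phase),
                 envelope = amplitude, rate_hz = rate_hz, t0 = t0),
            class = "band_signal")
}

# Von Mises sampler (Best & Fisher rejection method).
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  rhythmdecode:::wrap_pi(out)
}
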