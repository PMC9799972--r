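# Internal numeric helpers shared across modules.

#' @importFrom stats fft rnorm runif rpois sd median quantile wilcox.test
#'   binom.test complete.cases cor cor.test glm predict coef pnorm qnorm
#'   prcomp approx var rbinom rexp
#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# wrap angles into [-pi, pi)
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# Reflect-pad a signal to a 5-smooth length so fft() stays O(n log n).
pad_fast <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  if (m == n) return(list(x = x, n = n))
  pad <- x[n - seq_len(min(m - n, n - 1))]
  pad <- c(pad, rep(x[1], m - n - length(pad)))
  list(x = c(x, pad), n = n)
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  p <- pad_fast(x)
  x <- p$x
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = 0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(p$n)]
}

# Gaussian smoothing with reflected edges; sigma in samples.
# sigma = 0 returns the input unchanged.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 2L) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  pad_l <- x[pmin(n, (half + 1):2)]
  pad_r <- x[pmax(1L, (n - 1):(n - half))]
  xp <- c(pad_l, x, pad_r)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Circular Gaussian smoothing (wrap-around edges), used for phase-bin profiles.
gauss_smooth_circular <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 2L) return(x)
  n <- length(x)
  half <- min(n, max(1L, ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  xp <- c(x[(n - half + 1):n], x, x[1:half])
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Membership of time points in a set of half-open [start, end) windows.
# windows: two-column matrix or data frame (start, end).
in_windows <- function(t, windows) {
  windows <- as.matrix(windows)[, 1:2, drop = FALSE]
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(windows))) {
    out <- out | (t >= windows[i, 1] & t < windows[i, 2])
  }
  out
}

# Count of spikes falling in each half-open window.
count_in_windows <- function(times, windows) {
  windows <- as.matrix(windows)[, 1:2, drop = FALSE]
  vapply(seq_len(nrow(windows)), function(i) {
    sum(times >= windows[i, 1] & times < windows[i, 2])
  }, integer(1))
}

# Validate that a window specification is usable.
check_windows <- function(windows, arg = "windows") {
  windows <- as.matrix(windows)
  if (nrow(windows) == 0L) {
    abort(paste0("`", arg, "` is empty; at least one window is required."))
  }
  if (ncol(windows) < 2L || any(windows[, 2] < windows[, 1])) {
    abort(paste0("`", arg, "` must have start <= end in each row."))
  }
  windows[, 1:2, drop = FALSE]
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, alpha = 1, scale = 1) {
  if (n < 2L) return(rnorm(n, 0, scale))
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  X <- fft(white)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)          # symmetric frequency index
  shape <- 1 / f^(alpha / 2)
  shape[1] <- 0                    # remove DC
  x <- Re(fft(X * shape, inverse = TRUE) / m)[seq_len(n)]
  scale * x / sd(x)
}

# Derive a reproducible child seed below 2^31 from a base seed and a tag.
child_seed <- function(seed, k) {
  # double arithmetic stays exact below 2^53; result fits a 32-bit seed
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483587)
}
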