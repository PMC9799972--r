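#' Instantaneous band phase at spike times
#'
#' Evaluates the band phase of a reference LFP at each spike time inside
#' the analysis windows, by linear interpolation of the unwrapped phase
#' followed by re-wrapping. Spikes outside the signal support are dropped
#' (count reported as an attribute).
#'
#' @param unit A [spike_train()] or a numeric vector of spike times.
#' @param band_signal A [bandpass_zero_phase()] output from the region's
#'   reference tetrode.
#' @param windows Optional `(start, end)` windows (typically odor-sampling
#'   periods).
#' @return Numeric vector of phases in `[-pi, pi)`, with attribute
#'   `n_dropped`.
#' @export
spike_phases <- function(unit, band_signal, windows = NULL) {
  st <- if (inherits(unit, "spike_train")) unit$spike_times else
    as.numeric(unit)
  if (!is.null(windows)) {
    windows <- check_windows(windows)
    st <- st[in_windows(st, windows)]
  }
  t <- band_times(band_signal)
  inside <- st >= t[1] & st <= t[length(t)]
  dropped <- sum(!inside)
  st <- st[inside]
  ph_un <- unwrap_phase(band_signal$phase)
  out <- wrap_pi(approx(t, ph_un, xout = st)$y)
  attr(out, "n_dropped") <- dropped
  out
}

#' Rayleigh test for circular non-uniformity
#'
#' `R = |sum(exp(i theta))|`, `z = R^2 / n`, and the finite-sample
#' p-value `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, which
#' agrees with the large-sample approximation `exp(-z)` for moderate n
#' and small z.
#'
#' @param phases Numeric vector of phases (rad), n >= 1. Alternatively
#'   supply `n` and `z` directly to evaluate the p-value for a reported
#'   statistic.
#' @param n,z Optional sample size and Rayleigh Z replacing `phases`.
#' @return A tibble with `n`, `R`, `mvl` (= R/n), `z`, `p`.
#' @export
rayleigh_test <- function(phases = NULL, n = NULL, z = NULL) {
  if (is.null(phases)) {
    if (is.null(n) || is.null(z)) abort("Provide `phases`, or `n` and `z`.")
    R <- sqrt(z * n)
  } else {
    n <- length(phases)
    if (n < 1) abort("At least one phase is required.")
    R <- Mod(sum(exp(1i * phases)))
    z <- R^2 / n
  }
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble(n = n, R = R, mvl = R / n, z = z, p = min(1, p))
}

#' Circular mean phase
#'
#' Argument of the resultant vector `sum(exp(i theta))`; `NA` (flagged
#' with a warning) when the resultant length is numerically zero.
#'
#' @param phases Numeric vector of phases (rad).
#' @return Mean phase in `[-pi, pi)`, or `NA`.
#' @export
mean_phase <- function(phases) {
  if (length(phases) < 1) abort("At least one phase is required.")
  s <- sum(exp(1i * phases))
  if (Mod(s) < .Machine$double.eps * length(phases)) {
    warn("Resultant length is zero; mean phase undefined.")
    return(NA_real_)
  }
  wrap_pi(Arg(s))
}

# Mean vector length of a phase sample.
mvl <- function(phases) Mod(mean(exp(1i * phases)))

#' Invert a mean vector length to a von Mises concentration
#'
#' Solves `A(kappa) = I1(kappa) / I0(kappa) = r` numerically; the MVL of a
#' large von Mises sample converges to `A(kappa)`.
#'
#' @param r Observed MVL in `[0, 1)`.
#' @return Estimated concentration `kappa >= 0`.
#' @export
mvl_to_kappa <- function(r) {
  if (r <= 0) return(0)
  if (r >= 0.999) return(500)
  A <- function(k) besselI(k, 1) / besselI(k, 0)
  stats::uniroot(function(k) A(k) - r, c(1e-8, 500), tol = 1e-9)$root
}

#' Rate-adjusted MVL comparison (correct vs incorrect trials)
#'
#' Adjusts for the spike-count difference between conditions: draws
#' `n_incorrect` phases without replacement from the correct-trial phases,
#' computes the MVL of each of `n_boot` such draws, and reports the
#' one-sided p-value as the fraction of bootstrap MVLs at or below the
#' incorrect-trial MVL (testing correct more concentrated than incorrect).
#' When there are fewer correct than incorrect spikes the comparison is
#' direct, with a warning.
#'
#' @param phases_correct,phases_incorrect Spike phases per condition.
#' @param n_boot Number of downsampled draws (default 1000).
#' @param alternative `"correct_greater"` (default) or `"two.sided"`.
#' @return A tibble of class `mvl_comparison` with `mvl_incorrect`,
#'   `mvl_correct_boot` (mean of the bootstrap), `delta`, `p`, and the
#'   bootstrap values in `attr(, "boot")`.
#' @export
rate_adjusted_mvl_compare <- function(phases_correct, phases_incorrect,
                                      n_boot = 1000,
                                      alternative = c("correct_greater",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  n_inc <- length(phases_incorrect)
  if (n_inc < 10) warn("Fewer than 10 incorrect-trial spikes; unreliable.")
  m_inc <- mvl(phases_incorrect)
  if (length(phases_correct) < n_inc) {
    warn("Fewer correct than incorrect spikes; comparing directly.")
    boot <- rep(mvl(phases_correct), n_boot)
  } else {
    boot <- vapply(seq_len(n_boot), function(i) {
      mvl(sample(phases_correct, n_inc, replace = FALSE))
    }, numeric(1))
  }
  frac_le <- mean(boot <= m_inc)
  p <- if (alternative == "correct_greater") frac_le else
    2 * min(frac_le, mean(boot >= m_inc))
  out <- tibble(mvl_incorrect = m_inc, mvl_correct_boot = mean(boot),
                delta = mean(boot) - m_inc, p = p, n_spikes = n_inc)
  attr(out, "boot") <- boot
  class(out) <- c("mvl_comparison", class(out))
  out
}

#' Phase-locking census across units, bands, and regions
#'
#' Summarizes per-unit Rayleigh results: the fraction of units locked per
#' (cell class, band, phase region) with an exact binomial test of the
#' locked count against the chance level `alpha`; assignment of each
#' multi-region-locked unit to the region where it is locked most
#' significantly (smallest Rayleigh p, at the Bonferroni-adjusted
#' `cross_region_alpha` across the three regions); and a two-proportion
#' z-test between the two bands' locked fractions.
#'
#' @param results Tibble with one row per (unit, band, phase_region):
#'   columns `unit_id`, `cell_type`, `band`, `phase_region`, `p`.
#' @param alpha Single-region significance level (chance proportion).
#' @param cross_region_alpha Bonferroni-adjusted level for cross-region
#'   assignment (0.05 / 3).
#' @return A list with `census` (per class/band/region fractions and
#'   binomial p), `assignment` (per unit/band best region among
#'   significant lockings), and `band_test` (two-proportion z-test between
#'   bands).
#' @export
locking_census <- function(results, alpha = 0.05,
                           cross_region_alpha = 0.05 / 3) {
  census <- results %>%
    dplyr::group_by(.data$cell_type, .data$band, .data$phase_region) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_locked = sum(.data$p < alpha),
      fraction = .data$n_locked / .data$n,
      binom_p = binom.test(.data$n_locked, .data$n, p = alpha,
                           alternative = "greater")$p.value,
      .groups = "drop")

  assignment <- results %>%
    dplyr::filter(.data$p < cross_region_alpha) %>%
    dplyr::group_by(.data$unit_id, .data$band) %>%
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::select("unit_id", "band", best_region = "phase_region", "p")

  bands <- unique(results$band)
  band_test <- NULL
  if (length(bands) == 2) {
    k <- vapply(bands, function(b) {
      sum(results$p[results$band == b] < alpha)
    }, numeric(1))
    n <- vapply(bands, function(b) sum(results$band == b), numeric(1))
    p1 <- k[1] / n[1]; p2 <- k[2] / n[2]
    pp <- sum(k) / sum(n)
    se <- sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    zst <- if (se > 0) (p1 - p2) / se else 0
    band_test <- tibble(band1 = bands[1], band2 = bands[2],
                        frac1 = p1, frac2 = p2, z = zst,
                        p = 2 * pnorm(-abs(zst)))
  }
  list(census = census, assignment = assignment, band_test = band_test)
}

#' Per-session phase-locking table
#'
#' Runs [spike_phases()] + [rayleigh_test()] for every unit against the
#' band phase of each region's reference channel over the odor-sampling
#' windows. The reference tetrode per region is the one with the most
#' simultaneously recorded units (ties broken by lowest tetrode id).
#'
#' @param session A `session_record`.
#' @param bands Named list of band edges, e.g.
#'   `list(beta = c(20, 30), rr = c(7, 8))`.
#' @param min_spikes Minimum spikes in the windows to test a unit.
#' @return Tibble with one row per (unit, band, phase_region): `unit_id`,
#'   `region`, `cell_type`, `band`, `phase_region`, `n_spikes`, `mvl`,
#'   `z`, `p`, `mean_phase`.
#' @export
session_phase_locking <- function(session,
                                  bands = list(beta = c(20, 30),
                                               rr = c(7, 8)),
                                  min_spikes = 25) {
  ow <- odor_windows(session$trials)
  regions <- unique(vapply(session$lfp, function(s) s$region, character(1)))
  ref <- lapply(regions, function(rg) reference_channel(session, rg))
  names(ref) <- regions

  cls <- classify_units(session$units, run_epochs(session$position),
                        session$trials)
  rows <- list()
  for (bn in names(bands)) {
    bsigs <- lapply(ref, function(sig) bandpass_zero_phase(sig, bands[[bn]]))
    for (u in session$units) {
      for (rg in regions) {
        ph <- spike_phases(u, bsigs[[rg]], ow)
        if (length(ph) < min_spikes) next
        rt <- rayleigh_test(ph)
        rows[[length(rows) + 1]] <- tibble(
          unit_id = u$unit_id, region = u$region,
          cell_type = cls$cell_type[cls$unit_id == u$unit_id],
          band = bn, phase_region = rg, n_spikes = rt$n,
          mvl = rt$mvl, z = rt$z, p = rt$p,
          mean_phase = mean_phase(ph))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Reference channel for a region: tetrode carrying the most units
# (lowest tetrode id on ties).
reference_channel <- function(session, region) {
  sigs <- purrr::keep(session$lfp, ~ .x$region == region)
  if (length(sigs) == 0) abort(sprintf("No LFP for region %s.", region))
  counts <- vapply(sigs, function(sig) {
    sum(vapply(session$units, function(u) {
      u$region == region && u$tetrode_id == sig$tetrode_id
    }, logical(1)))
  }, numeric(1))
  tids <- vapply(sigs, function(s) s$tetrode_id, integer(1))
  sigs[[order(-counts, tids)[1]]]
}
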