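---
title: "Methods: rhythm coordination and ensemble choice decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm coordination and ensemble choice decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmdecode)
```

## The task and the data model

rhythmdecode analyzes multi-region electrophysiology recorded while a rat
performs an odor-cued two-choice T-maze task. On each trial the animal
holds its nose in an odor port (minimum 0.5 s; the hold is the
*odor-sampling / decision-making period*), then runs down an 81 cm stem
and a 42 cm reward arm (a 123 cm linearized outbound route) to the reward
well matching the sampled odor. A session bundles LFP channels from
hippocampal CA1, prefrontal cortex (PFC) and olfactory bulb (OB,
nominally 1.5 kHz), per-unit spike trains with rate and spike-width
summaries, a trial table, a 30 Hz position trace, and optionally a nasal
thermocouple trace that tracks sniffing.

Conventions used everywhere:

* one session clock in seconds starting at 0;
* all intervals are half-open `[start, end)`, so a spike exactly at
  odor-port exit belongs to the run period, never to the odor period —
  this prevents double counting at boundaries;
* bins are 0-based: bin *b* covers `[b*delta, (b+1)*delta)`;
* trials with a hold under 0.5 s (inclusive threshold: exactly 0.5 s is
  kept) or without a subsequent reward-well visit are excluded from every
  analysis;
* speed is derived by central differences of Gaussian-smoothed
  (sigma = 2 samples) coordinates;
* session bundles are plain CSV directories; doubles are written with 17
  significant digits so write → read → write is byte-stable.

## Band signals and spectral estimates

`bandpass_zero_phase()` applies a 4th-order Butterworth band-pass forward
and backward (zero net phase) and takes amplitude, phase and envelope
from the analytic (Hilbert) signal. Phase 0 is the oscillation peak. Two
numerical points matter:

* a direct IIR design at 1.5 kHz is ill-conditioned for the 7–8 Hz
  respiratory band (the normalized band edges are ~0.01); the filter
  therefore runs on an internally decimated copy whenever the upper band
  edge is below 1/20 of the sampling rate, and the filtered trace,
  envelope and unwrapped phase are interpolated back to the original
  sample times;
* all FFTs (Hilbert transform, pink-noise synthesis, decimation) pad to
  5-smooth lengths, because R's mixed-radix FFT degrades to quadratic
  cost at near-prime lengths typical of whole-session traces.

`multitaper_spectrogram()` and `multitaper_coherogram()` use Slepian
tapers computed from the standard symmetric tridiagonal eigenproblem.
Defaults: 500 ms windows, 50 ms steps, time-bandwidth 3, 5 tapers —
a ±6 Hz resolution bandwidth, appropriate for separating the 7–8 Hz
respiratory rhythm (RR) from 20–30 Hz beta. Power can be z-scored per
frequency row against the whole aligned epoch. Coherence of independent
noise has a positive bias floor of roughly 1/(tapers × events), which the
tests verify by simulation.

Condition contrasts (post- vs pre-odor, odor vs reward, correct vs
incorrect) are Wilcoxon signed-rank tests on within-session differences;
correct-vs-incorrect comparisons first draw one seeded random subsample
of correct trials to match the incorrect-trial count. The odor-vs-air
comparison uses a bootstrap: odor trials are down-sampled with
replacement to the air-trial count 1000 times and the one-sided p-value
is the fraction of bootstrap means at or below the observed air mean,
floored at 1/1000.

## Cross-frequency coupling

RR-phase → beta-amplitude coupling uses the Kullback–Leibler modulation
index: 18 phase bins of 20°, mean beta amplitude per bin normalized to a
probability vector *P*, and `MI = KL(P || uniform)/log 18` in [0, 1]. The
natural log is used; the base cancels in the ratio. A 1e-12 epsilon
guards the entropy against empty-adjacent bins; an empty bin is filled by
circular neighbor interpolation and flagged. Significance comes from
shuffling the trial assignment of the phase series against the amplitude
series (keeping within-trial structure) with the +1-corrected permutation
p-value.

A structural point the tests document: band-pass filtering beta at 20–30
Hz removes amplitude-modulation sidebands beyond ±5 Hz, and RR runs at
~7.5 Hz, so most of the per-cycle modulation is attenuated by the filter
itself and measured MI values are small (~1e-5 to 1e-4 on the synthetic
sessions). MI remains near zero without coupling and strictly monotone in
the generated coupling depth, which is what the shuffle test and the
rank-order recovery rely on; absolute MI magnitudes are not interpreted.

## Events and behavior

Sharp-wave ripples: each CA1 channel is filtered at 150–250 Hz; the
Hilbert envelope is smoothed with a 4 ms Gaussian; events are contiguous
periods above mean + 3 SD lasting at least 15 ms on at least one tetrode,
with boundaries extended outward to the mean crossing and overlapping
per-tetrode events merged. Detection is invariant to amplitude scaling.
On pure Gaussian noise this detector produces ~0.8 events/min at 1.5 kHz;
the envelope smoothing, which suppresses single-sample crossings, slightly
*lengthens* threshold excursions, so the false-event rate is not zero and
is reported by simulation in the tests.

Run epochs are maximal intervals with speed > 3 cm/s. The turn direction
at odor-port exit is the sign of the initial lateral displacement within
0.5 s of port exit, compared with the chosen arm side; one-sided binomial
tests against 0.5 are run separately for correct and incorrect trials.
Sniff rate is the peak count of the 2–12 Hz filtered thermocouple trace
per window.

## Single units

Putative interneurons have mean rate > 7 Hz **and** spike width < 0.3 ms
(conjunctive); everything else is pyramidal. `active` requires ≥ 100
run-epoch spikes; `odor_active` requires at least as many odor-period
spikes as included trials. Task responsiveness is a Wilcoxon signed-rank
test on trial-matched (post − pre) rate differences per odor (pre-window
duration equals that trial's hold), at alpha 0.05 per odor, uncorrected —
two separate tests, as responsiveness to either odor qualifies.

Choice selectivity is `SI = (l1 - l2)/(l1 + l2)` with rates computed as
total spikes over total odor-period time per odor on correct trials
(duration weighting avoids amplifying short-trial noise). The null
shuffles odor labels across correct trials; the selectivity flag uses the
1.5 SD rule on that null, and a two-sided permutation p-value is reported
alongside for calibrated alpha-level decisions. `si_incorrect` applies
the same odor-label convention to incorrect trials, so a unit following
the *chosen side* flips sign — the population-level anticorrelation
between correct- and incorrect-trial SI is the signature of choice (not
odor) coding.

The jitter-corrected cross-correlogram uses lags −150..150 ms in 2.5 ms
bins with lag = t(PFC) − t(CA1), so positive peaks mean CA1 leads. The
null jitters each PFC spike independently by ±50 ms (preserving counts
and the 50 ms-smoothed rate); the pointwise z-score is reported per lag.
For the *significance flag* the observed max |z| within ±100 ms is
compared against the same maximum computed on each jitter surrogate: a
pointwise |z| > 1.96 rule over 80 correlated lags would flag nearly every
independent pair, whereas the max-statistic test controls the family-wise
rate at the nominal level (the calibration suite verifies ~5%).
Significant CCGs are smoothed with a sigma = 1 bin Gaussian for display.

## Phase locking

Spike phases are linear interpolations of the unwrapped reference-channel
band phase at spike times, pooled over odor-sampling windows; the
reference tetrode per region is the one carrying the most units (ties to
the lowest tetrode id). The Rayleigh statistic is `R = |sum exp(i
theta)|`, `z = R^2/n`, with the finite-sample p-value
`exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`; the tests pin this formula
to published worked examples and to its `exp(-z)` large-n limit. The mean
vector length MVL = R/n estimates the von Mises concentration through
`A(kappa) = I1(kappa)/I0(kappa)`, inverted numerically by
`mvl_to_kappa()`.

Correct-vs-incorrect locking comparisons downsample correct-trial spikes
(without replacement within each of 1000 draws) to the incorrect-trial
spike count before comparing MVLs, removing the rate confound. The
population census reports locked fractions per cell class, band and
region with exact binomial tests against the chance level, assigns
multi-region-locked units to their most significant region at the
Bonferroni-adjusted alpha of 0.05/3, and compares bands with a
two-proportion z-test.

## Ensemble decoding

The rate matrix bins spikes at 100 ms over 0–1 s from the alignment
event; sessions with fewer than four task-responsive units are skipped.
PCA is fit on the pooled trial × bin matrix (bins as observations — the
fitting matrix is not dictated by convention, and pooling both choices
keeps the projection label-agnostic); per-choice mean trajectories are
projected onto the first three PCs and the per-bin Euclidean distance is
compared with a pointwise 95% band from label shuffles. The
discrimination time is the first bin exceeding the band. Because the band
is pointwise, the per-bin false-exceedance rate is ~5% but the
probability that *some* bin exceeds is higher; the calibration suite
reports the per-bin rate. The even/odd control (distance between
half-sample means within each choice) is scaled by 1/sqrt(2) because
half-sample means carry twice the variance of the full-class means the
null uses; without this the control would sit systematically above the
band on pure noise.

The choice GLM is a binomial model (logit link by default; a log-link
binomial is available — the literature's "GLM with a log link" for a
binary outcome is ambiguous, and the log-binomial fit falls back to logit
on non-convergence) on per-unit mean counts in cumulative windows 0–0.1 …
0–1.0 s, with stratified five-fold cross-validation and a shuffled-label
null. The primary per-window p-value is the permutation p of the mean
cross-validated accuracy among the shuffled-label runs, which is
exchangeable under the null and therefore calibrated; the rank-sum of
fold accuracies against null accuracies is reported alongside
(`p_ranksum`), but folds share training data, so its nominal level is
unreliable (the calibration suite measured ~0.12 at alpha 0.05).

The Bayesian decoder is memoryless Poisson: training rates `f_i(X)` per
unit and choice (floored at 0.01 Hz so a silent unit cannot zero a
likelihood), and decoding maximizes
`sum_i n_i log f_i(X) - tau sum_i f_i(X)` with a uniform prior; ties
decode to the choice with more training trials. The tests verify log-space
decoding against direct evaluation of the likelihood in linear space on
1000 random small ensembles. For spatial decoding the outbound route is
cut into five 24.6 cm quintiles; run activity starts 0.5 s after
odor-port exit while speed > 3 cm/s, `tau` is the trial's occupancy of
the quintile, cross-validation is five-fold as in the GLM, and the
p-value per quintile uses the Gaussian mean/sd of 200 label-shuffled
decoders.

## Spatial maps

2-D rate maps divide spikes per 2 cm pixel by unsmoothed occupancy
(speed > 3 cm/s epochs, odor and reward windows excluded) and smooth the
quotient with a sigma = 2 pixel Gaussian. Linearized tuning curves use
100 bins (1.23 cm) along each origin→destination route, smoothed with
sigma = 2 bins. Place fields require a 1 Hz peak; bounds flood-fill
outward to 25% of the peak (ties between equal peaks go to the lowest
bin); significance requires the peak to exceed mean + 2 SD of a 500-draw
bootstrap that circularly shifts each run's spikes within the run
(preserving per-run counts), plus field coverage below 75% of the route.
Trajectory selectivity is the Pearson correlation of the left and right
tuning curves against a route-identity shuffle (selective below the 5th
percentile), plus a rate-based index `(rL - rR)/(rL + rR)` over run
windows that end at the goal or after speed stays below 3 cm/s for 0.5 s.

## The synthetic-session generator

`synth_session()` generates sessions with known ground truth. Defaults
are the study conditions: 100 trials per session, 77% accuracy, holds of
0.5 s plus a gamma excess averaging 0.82 s, ~5% premature trials, RR at
7.5 Hz, a 25 Hz beta carrier (band center) whose amplitude is modulated
by RR phase with depth `pac_strength` and doubled during odor sampling,
1/f noise (exponent 1, amplitude set for odor-period beta SNR ≈ 2),
ripple bursts (200 Hz, 50–80 ms) at reward wells at 0.5 Hz shared across
CA1 channels, sniffing at 6.2 Hz pre-odor and 7.1 Hz during odor, and a
T-maze path run at 30 cm/s with a lateral turn toward the chosen side at
port exit.

Units are inhomogeneous Poisson processes sampled by thinning (exact
under a bounded intensity). The von Mises phase-locking gain is
normalized as `exp(kappa cos(theta - mu))/I0(kappa)` so concentration
changes spike timing, not rate. Pyramidal cells form two ensembles:

* **choice units** — odor-active, rate scaled by `1 ± SI` by the chosen
  side during the odor period and for a 1 s transient after port exit,
  flat low rate on the track;
* **place units** — odor-inactive, Gaussian place field (centers uniform
  along the route, full widths ~14–40 cm) on one preferred outbound
  route.

This separation mirrors the central empirical finding the decoding
analyses are designed to show: the odor-period choice code is carried
transiently past the decision point by one ensemble, while a distinct,
spatially modulated ensemble carries choice information along the
trajectory. With a single mixed ensemble the odor-trained decoder would
trivially read route-selective spatial firing in every quintile and the
dissociation would be unobservable. Interneurons (rate > 7 Hz, width
< 0.3 ms) are phase-locked throughout and not selective.

What the generator does **not** emulate: theta rhythm and phase
precession, ripple-content replay, behavioral lapses in hold timing
correlated with accuracy, electrode drift, or cross-unit correlations
beyond shared rhythms. Passing parameter-recovery tests on these sessions
shows the pipeline correctly inverts its own generative assumptions — it
does not certify performance on real recordings.

## Calibration and recovery experiments

`calibrate_pac/si/ccg/rayleigh/glm/pca()` simulate no-effect data and
report false-positive rates at alpha 0.05 over seeded runs; problem sizes
(10 trials × 0.8 s at 250 Hz for PAC; 40 trials at 8 Hz for SI; two 5 Hz
× 60 s Poisson trains for the CCG; 150 uniform phases for Rayleigh; 40
trials × 8 Poisson units for the GLM and PCA) are chosen so 200 runs
complete in a few minutes on one CPU. `recover_parameters()` runs 20
sessions at the default behavioral conditions with the LFP rate reduced
to 400 Hz (RR and beta are fully resolved; ripples are not needed there)
and the PAC depth swept over a grid, then reports Spearman correlations
between estimated and planted SI, kappa, PAC strength, and field
centers/widths, plus the mean absolute field-center error in bins.
`decoding_patterns()` reproduces the quintile dissociation above as an
ordering check.

`scripts/acceptance.R` re-runs all of these from scratch against the
installed package and writes the resulting numbers as JSON.

## Known limitations

* MI magnitudes on band-filtered data are attenuated (see above); only
  their ordering and null behavior are meaningful.
* The GLM rank-sum compares cross-validated fold accuracies, which share
  training data; the calibration suite measures the realized level
  rather than assuming the nominal one.
* The PCA discrimination band is pointwise; family-wise exceedance is
  larger, and discrimination *times* should be read with that caveat.
* Place-field width estimates include the smoothing kernel's widening;
  recovery is assessed by rank correlation, not absolute agreement.
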