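---
title: "Methods: simulating and analysing a CMR/BMLD masking study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a CMR/BMLD masking study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

comask implements the complete computational apparatus of a combined
comodulation masking release (CMR) / binaural masking level difference
(BMLD) experiment: calibrated stimulus synthesis, adaptive
masked-threshold estimation against simulated listeners, the auditory
evoked potential (AEP) change-complex chain, and rank-based analysis of
salience ratings. Every stage can be exercised closed-loop on synthetic
data whose ground truth is known, so the statistical machinery can be
certified independently of any human recordings. This vignette documents
the models, the tunable parameters, and the design choices made where the
design was genuinely open.

## The stimuli

The signal is a 700-Hz tone of 300 ms (20-ms raised-cosine ramps)
presented in the last 300 ms of a 900-ms masker, either diotically
(interaural phase difference, IPD, of 0°) or dichotically (IPD 150°, the
right channel leading). Three maskers are synthesized:

* **UN** — five 24-Hz-wide noise bands at 50 dB SPL each, centered at
  300, 400, 700, 1000 and 1100 Hz, with statistically independent
  envelopes;
* **CM** — the same five bands built from one shared low-frequency
  modulator, so their intensity fluctuations are comodulated;
* **BB** — a single 824-Hz-wide band centered at 700 Hz at 60 dB SPL
  overall.

Each band is the product of a random-phase sinusoidal carrier and a
low-pass noise synthesized in the frequency domain: uniform numbers in
±0.5 are assigned to the real and imaginary parts of every 1-Hz component
up to the cutoff, with no DC component, and transformed to the time
domain. A band of width *W* uses a modulator cutoff of *W*/2, since the
carrier multiplication doubles the one-sided bandwidth. The 1-s buffer is
truncated to 900 ms; truncation slightly widens the effective bandwidth,
so spectral-confinement assertions are made on the generation spectrum.

**Calibration.** A digital waveform has no absolute sound pressure, so
the package fixes one convention — digital RMS 1.0 ≡ 100 dB SPL
(`calibration()`) — and scales every component to its target RMS exactly,
per realization. Ramps are applied *before* this scaling so the delivered
full-duration level is bit-exact; with the reverse order the
raised-cosine ramps would shave about 0.12 dB off the nominal level.

**Open choices.** The IPD is applied wholly to the right channel rather
than split ±75°; tone-in-noise detection statistics are invariant to the
split. Carrier phases are independent across bands in all masker types
(the comodulated masker shares only its modulator); sharing the carrier
phase as well is exposed as `share_carrier_phase` for comparison.

## The adaptive procedure

Masked thresholds come from a three-interval, three-alternative
forced-choice one-up two-down staircase: the level drops after two
consecutive correct responses and rises after every error, converging on
the 70.7%-correct point of the psychometric function. The step starts at
8 dB, halves after each *lower* reversal down to 1 dB, and the track ends
after six further reversals at 1 dB; the run's threshold is the mean
level at those six reversals. Four runs are collected per condition and
the final threshold is the mean of the last three. From the final
thresholds, CMR = thr(UN) − thr(CM) at fixed IPD and
BMLD = thr(IPD 0) − thr(IPD 150) at fixed masker.

**The virtual listener** (`simulated_listener()`) has
P(correct) = g + (1 − g − λ)·F((L − m)/s) with guess rate g = 1/3,
lapse rate λ (default 0), logistic F and spread s (default 4 dB); the
midpoint m is placed per condition so that P equals 0.707 exactly at the
configured level t707. Parametrizing the listener directly by its 70.7%
point keeps recovery tests non-circular in every other psychometric
parameter: the staircase must find t707 whatever the slope.

**Two timing choices deserve record.** First, the step is halved *after*
the move that completes a lower reversal: the recovery move away from a
large-step undershoot uses the old (larger) step. Under the alternative
reading (halve first, recover with the new step), deep early undershoots
persist into the 1-dB phase and bias six-reversal estimates by almost
−1 dB. Second, the default start level is the listener's configured
70.7% point itself. Starting 10 dB above — natural for human listeners,
whose threshold is unknown — injects an approach-phase transient of
about +0.5 dB into so short a track; since the virtual observer exists to
certify the estimator, the default isolates the rule's asymptotic
behavior, and any explicit start level can be configured
(`staircase_config(start_level = )`). Both effects cancel in CMR and
BMLD, which are differences of identically-run tracks.

Tracks that hit the safety bounds repeatedly or exhaust the trial budget
(default 200) are flagged non-converged rather than silently truncated;
a non-converged run among the last three raises an error requesting a
rerun (the first, discarded run may fail freely).

## The evoked-potential chain

Epochs span [−150, 1050) ms around masker onset at 1024 Hz; the window is
half-open on the right and instants round toward zero, conversions
centralized in `ms_to_sample()` / `ms_window_to_offsets()` (an epoch is
1229 samples). The chain, in order:

1. **artifact rejection** — a sweep is discarded iff any sample in any
   recorded channel exceeds ±100 μV *strictly* (a sample at exactly
   100 μV is kept; the boundary is open in the design). Rejection runs on
   the raw epochs so that brief high-amplitude excursions cannot be
   smoothed below threshold by the later filter.
2. **linear detrend** — a least-squares line fitted on
   [450, 600] ∪ [900, 1050] ms only (the 150 ms before the signal onset
   and the 150 ms after the stimulus ends) is subtracted from the whole
   sweep. The post-stimulus reading of "150 ms after the stimulus" is
   [900, 1050] ms; the alternative (after stimulus *onset*) would overlap
   the masker-onset response and is rejected, though it is an
   interpretation.
3. **zero-phase low-pass** — second-order Butterworth at 20 Hz applied
   forward and backward (`signal::filtfilt`), doubling the effective
   order and cancelling the phase response.
4. **baseline correction** on the 150-ms pre-stimulus period.
5. **iterative weighted averaging** — starting from the arithmetic mean,
   each sweep's noise power is estimated as the variance of its residual
   from the current average on the analysis channel (Cz); weights
   proportional to inverse noise power give the next weighted mean,
   iterated to a fixed point (relative change < 10⁻⁶, 50-iteration cap).
   The cited iterative method is not specified by formula in the source
   literature available here; this standard inverse-residual-variance
   fixed point is declared, not asserted identical. Identical sweeps
   (zero residual variance) fall back to uniform weights.
6. **change-complex extraction** — the averaged AEP over [450, 1050] ms,
   re-baselined on [450, 600] ms, latencies re-expressed relative to the
   signal onset at 600 ms.
7. **peak scan** — N1 is the minimum-type extremum (first derivative
   crossing zero, − to +) in [90, 190] ms and P2 the maximum-type
   extremum in [180, 290] ms; among multiple candidates the largest
   magnitude wins. A wrong-polarity candidate, an empty window, or an N1
   latency at or beyond the P2 latency (possible in the 180–190 ms
   window overlap) leaves the peak missing and sets `review_flag` — the
   machine-readable analogue of manual verification by visual
   inspection.

## The synthetic-data generators

`make_cohort()` draws per-listener 70.7% levels as grand values plus
Gaussian between-listener offsets (default SD 3 dB). The grand defaults
encode the study's threshold pattern: UN₀ 48.9, CM₀ 38.2, UN₁₅₀ 35.0,
CM₁₅₀ 26.7 dB SPL, BB₀ equal to UN₀ (the broadband masker is designed to
mask like the uncorrelated one) and BB₁₅₀ 11.5 dB below BB₀.

`make_sweeps()` builds each sweep as a masker-onset response (N1 ≈
100 ms, P2 ≈ 200 ms re masker onset) plus a change complex (N1 ≈ 130 ms,
P2 ≈ 230 ms re signal onset) from Gaussian-windowed deflections (widths
20–30 ms), scaled by the saturating law A(SL) = A_max · SL/(SL + 10 dB)
for SL > 0 and absent at or below masked threshold, embedded in
first-order autoregressive background noise (coefficient 0.95, default
15 μV RMS) with optional slow drift and Bernoulli-injected artifact
excursions. No quantitative amplitude-versus-level law or single-sweep
noise statistic is published for this paradigm; these are configuration,
not claims, and must not be read as reproducing any real listener's
amplitudes. The generator returns its exact ground truth (template
amplitudes, latencies, artifact flags) for closed-loop tests.

`make_ratings()` produces 0–10 endpoint-anchored salience ratings,
monotone in sensation level via the same saturating growth law, with
condition offsets either zero ("SL-ordered" listeners) or derived from
the conditions' masked thresholds ("SMR-ordered" listeners, rated by
physical signal-to-masker ratio) — the two archetypes observed
behaviorally. Ratings are clipped to the scale; below-threshold levels
concentrate near zero.

What the generators do *not* emulate: biophysical EEG (dipoles, volume
conduction, realistic spatial covariance), listener-specific
idiosyncrasies beyond the two rating archetypes, and acquisition-filter
coloration beyond the AR(1) model. Passing recovery tests therefore
certifies the *pipeline*, not any claim about real cortical responses.

## Salience analysis

Ratings are aggregated to medians and interquartile ranges over blocks,
then medians over listeners. Two Friedman rank tests probe the 6 × 6
grand-median matrix (conditions × sensation levels): levels as columns
for the level effect, then the transposed matrix for the condition
effect — two separate tests, since the Friedman procedure cannot assess
interactions. Ties take mid-ranks with the standard tie-corrected
statistic

χ² = (k − 1) Σⱼ (Rⱼ − n(k+1)/2)² / (Σᵢⱼ rᵢⱼ² − nk(k+1)²/4),

which reduces to 12/(nk(k+1)) ΣRⱼ² − 3n(k+1) without ties; p-values use
the asymptotic χ² reference with k − 1 degrees of freedom (df = 5 for the
6 × 6 arrangement), with a within-row permutation null available as a
verification mode for small matrices. Whether the original analysis used
the grand-median 6 × 6 matrix or stacked per-listener medians is
ambiguous; both arrangements are supported
(`run_experiment3_tests(arrangement = )`), grand-median being the
default. A ratings file loader excludes the first (training) block by
default. The χ² values of the original human dataset are not
reproducible without its raw ratings and are not a target of this
package.

## Numerical conventions and degenerate inputs

* All randomness flows from explicit seeds; one global seed feeds named
  substreams (stimuli, staircase, eeg, ratings) in the experiment
  drivers, so each stage reruns identically in isolation.
* Level scaling is exact per realization; `measure_level()` of an
  all-zero vector reports −Inf rather than erroring.
* Zero-variance residuals in the weighted average fall back to uniform
  weights; an all-rejected sweep set is a hard error naming the
  condition.
* Missing cells in a Friedman matrix are an error (no imputation);
  identical columns give statistic 0 and p = 1.
* WAV export quantizes to 16-bit PCM at 44.1 kHz with clipping warnings;
  the calibration headroom (full scale = 100 dB SPL, stimuli ≤ 60 dB)
  keeps synthesis far from the clip point.

## Problem sizes used by the test suite

The validation suite certifies the staircase with 500 tracks per check
(mean-threshold recovery to within 0.5 dB; the converged level probed
with 10⁵ Bernoulli draws against the 70.7% definition), the evoked
pipeline with one 400-sweep set per end-to-end check (recovered N1/P2
amplitudes within 10% and latencies within 8 ms of generator truth, at a
conservative single-sweep SNR of about +1 dB — the autoregressive
background lies almost entirely below the 20-Hz cut-off, so filtering
cannot remove it and the averaging budget alone carries the recovery),
and the Friedman implementation with 10⁴ null replicates (empirical size
required to lie in [0.03, 0.07] at α = 0.05). These sizes make the whole
suite run in well under a minute while keeping Monte-Carlo error small
against each tolerance.

## Known limitations

* The staircase's six-reversal estimate retains a small positive
  equilibrium bias (≈ +0.1 dB for a 4-dB logistic slope); differences
  (CMR, BMLD) are unaffected.
* The 20-Hz zero-phase filter attenuates 20–25-ms-wide deflections by
  3–5%; recovered amplitudes inherit that bias exactly as the original
  analysis would.
* The weighted-average weighting scheme is one reasonable reading of an
  under-specified method; alternatives (e.g. noise estimated from
  pre-stimulus intervals only) would differ in detail.
* Salience generation is phenomenological; it supports power and
  type-I-error studies of the analysis, not inference about perception.

## A minimal session

```{r, eval = FALSE}
library(comask)

# Experiment 1: thresholds, CMR, BMLD for a synthetic cohort
cfg <- default_config(seed = 1)
exp1 <- run_experiment1(cfg)
exp1$summary

# Experiment 2: synthetic sweeps through the AEP chain
gen <- make_sweeps("CM_0", sensation_level = 20, n_sweeps = 400, seed = 1)
res <- process_sweeps(gen$sweeps)
tidy(res$peaks)
autoplot(res$change_complex, peaks = res$peaks)

# Experiment 3: ratings, medians, Friedman tests
exp3 <- run_experiment3(cfg)
tidy(exp3$tests)
```
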