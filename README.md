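# comask

Simulation and analysis pipeline for combined **comodulation masking
release (CMR)** / **binaural masking level difference (BMLD)**
experiments in auditory psychophysics and electrophysiology.

Detecting a tone in noise becomes easier when the masker's intensity
fluctuations are coherent across frequency bands (comodulation) or when
the tone differs interaurally from the masker (a dichotic signal in a
diotic masker). The two effects are quantified as threshold differences:

* **CMR** = thr(UN) − thr(CM): masked threshold with *uncorrelated*
  multi-band noise minus threshold with *comodulated* noise, at the same
  signal interaural phase difference (IPD);
* **BMLD** = thr(IPD 0°) − thr(IPD 150°): diotic minus dichotic
  threshold, in the same masker.

comask renders the six stimulus conditions (UN/CM/BB maskers × IPD
0°/150°) as calibrated stereo waveforms, estimates masked thresholds with
a one-up two-down three-alternative forced-choice staircase (convergent
on the 70.7% point of the psychometric function) run against configurable
logistic virtual listeners, processes multichannel EEG sweeps into the
auditory evoked potential (AEP) *change complex* — the N1/P2 deflections
following the onset of the signal within the ongoing masker — via linear
detrending, zero-phase 20-Hz low-pass filtering, ±100 μV artifact
rejection and iterative inverse-noise-power weighted averaging, and
analyses 0–10 salience ratings with tie-corrected Friedman rank tests.
Seed-deterministic synthetic-data generators (listener cohorts, EEG
sweeps with known ground truth, rating tables) make every stage testable
closed-loop.

## Worked example

```r
library(comask)

## Masked thresholds, CMR and BMLD for a synthetic 8-listener cohort
exp1 <- run_experiment1(default_config(seed = 1))
exp1$summary
#> <masking_release_summary>
#>   grand-average thresholds (dB SPL):
#>   BB_0 BB_150   CM_0 CM_150   UN_0 UN_150
#>   50.7   36.7   37.2   25.7   51.9   35.8
#>   CMR / BMLD (dB, grand average):
#>   cmr_diotic cmr_dichotic bmld_un bmld_cm bmld_bb
#> 1       14.6         10.1      16    11.5    14.1
```

Each listener's 70.7%-correct level per condition is drawn around the
configured grand pattern (UN₀ 48.9, CM₀ 38.2, UN₁₅₀ 35.0, CM₁₅₀ 26.7 dB
SPL, …) with a 3-dB between-listener spread, then measured by four
staircase runs per condition (mean of the last three). With eight
listeners the grand averages — and hence the CMR/BMLD estimates —
legitimately wobble by one to two dB around the configured values; the
acceptance script below removes the cohort sampling to certify the
estimator itself.

```r
## One adaptive track in detail
li <- simulated_listener(c(CM_0 = 38.2))
run_track(li, "CM_0", seed = 2)
#> <staircase_track> CM_0: 33 trials, 11 reversals, threshold 37.37 dB SPL

## Synthetic EEG sweeps through the AEP chain
gen <- make_sweeps("CM_0", sensation_level = 20, n_sweeps = 400, seed = 1)
res <- process_sweeps(gen$sweeps)
res$peaks
#> <peak_set> N1: 127.5 ms, -3.20 uV | P2: 227.1 ms, 4.61 uV
```

The generator's ground truth for this set is N1 = −3.33 μV at 130 ms and
P2 = 4.00 μV at 230 ms: at the default, deliberately realistic
single-sweep noise (15 μV RMS autoregressive background) a 400-sweep
weighted average recovers the peaks to within a few hundred nanovolts
and ~3 ms. `autoplot(res$change_complex, peaks = res$peaks)` draws the
extracted change complex with the detected peaks.

```r
## Salience ratings and the two Friedman tests
exp3 <- run_experiment3(default_config(seed = 1))
exp3$tests
#> <salience_tests>
#>   <friedman_rank_test> levels-as-columns: chi^2(5) = 29.24, p 2.08e-05 (6 x 6, chisq)
#>   <friedman_rank_test> conditions-as-columns: chi^2(5) = 7.38, p 0.194 (6 x 6, chisq)
```

The default rating generator grows salience with sensation level and
applies no condition offsets, so the level effect is strong and the
condition effect is null — exactly what the pair of tests reports.

All result types have `tidy()` / `glance()` methods returning tibbles
and `autoplot()` diagnostics; `render_stimuli()` writes the calibrated
stereo WAV files with a JSON manifest of seeds and measured levels.

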