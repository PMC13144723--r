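# sleepscope

Sleep in larval zebrafish is defined behaviorally — locomotor speed below
0.5 mm/s sustained for at least a minute — but quiescence is not one
state. The eyes give it away: some sleep episodes carry frequent,
temporally regular conjugate saccades with short fixations (QEM-1),
others sparse saccades whose post-saccadic angle decays steeply (QEM-2)
or holds long and static (QEM-3), and others no eye movements at all
(QNEM). `sleepscope` implements the complete analysis chain for this
partition and for the neural dynamics of the eye-movement sleep state:

* **Eye tracking** on egocentric head images: difference-of-Gaussians
  filtering, axis-projection eye localization with a bimodal mixture, and
  orientation from second central moments.
* **Saccade detection and scoring**: 200-s detrend, 1.5-s median filter,
  exact fused-lasso (total-variation) denoising with λ = 0.25, candidate
  peaks in the product of left/right eye velocities, interocular
  correlation and residual selection, then decay slope, fixation duration
  (33% amplitude recrossing) and peak speed on the raw trace.
* **Substate classification**: 1-min bins of sleep periods, features
  (count, mean slope, mean fixation), a 3-component diagonal Gaussian
  mixture with diagonally-dominant initialization, a 2e-5 variance floor
  and model order chosen by SABIC = −2 log L + p log((n+2)/24); bins
  without saccades are QNEM by rule.
* **Circadian/luminosity gating**: a latent-variable network
  (4 → 24 → 1 → 24 → 5 softmax) mapping lights, introduction day and a
  24-h cosine/sine pair to five state probabilities, with repeated
  5-fold cross-validation over fish and input-ablation analysis.
* **Neural post-processing and dynamics**: duplicate-ROI merging,
  coverage filtering, exponential bleach correction, transient-event
  detection; per-neuron encoding regression with shuffle-based partial
  models; bounded exponential ramp fits over relative time; permutation
  anatomical enrichment; state-restricted PCA; a trajectory-entanglement
  statistic (self-crossings per second); and elastic-net decoding of
  relative time with leave-one-period-out validation, gain correction,
  circular-shift and behavior-only controls.
* **A synthetic-data generator** that emulates the statistical structure
  of all of the above — state schedules, per-substate saccade processes
  built from the published kinematic constants, swim bouts, head-ROI
  image stacks, and neural populations with suppression, ramping, events,
  bleaching and missing data — with ground-truth logs, so every stage is
  testable end-to-end without external recordings.

The methods vignette (`vignettes/sleepscope-methods.Rmd`) documents the
models, the free parameters and every place where an underdetermined
detail had to be fixed.

## Worked example

Simulate four hours of behavior on a mixed state schedule, run the full
behavioral chain, and report substate occupancy:

```r
library(sleepscope)

sch <- make_schedule(4 * 3600,
                     occupancy_targets = c(Wake = 0.2, QEM1 = 0.35,
                                           QEM2 = 0.2, QEM3 = 0.15,
                                           QNEM = 0.1),
                     seed = 2, mean_segment_s = 400)
beh     <- synth_behavior(sch, fs_hz = 50, seed = 2)
periods <- detect_sleep(beh$speed$speed_mm_s, 50)
events  <- detect_saccades(beh$trace, "multi", period_ends_s = periods$end_s)
bins    <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i)
             bin_period(periods$start_s[i], periods$end_s[i])))
feats   <- featurize(bins, events)
gmm     <- fit_substate_gmm(feats, seed = 1, sweep = FALSE)
labels  <- label_series(classify_bins(feats, gmm), 4 * 3600)
compute_occupancy(labels)
```

which prints

```
5 sleep periods, 1913 accepted saccades
mean fixation 5.10 s, mean decay slope 0.50 deg/s, mean peak speed 672 deg/s
  state frac_total frac_sleep
2  QEM1      0.465      0.592
3  QEM2      0.184      0.233
4  QEM3      0.054      0.069
5  QNEM      0.083      0.106
```

`frac_total` is the fraction of recording time per state; `frac_sleep`
restricts the denominator to sleep (the four quiescent states). The event
table carries per-saccade onset, direction, amplitude, peak speed
(deg/s), decay slope (deg/s), fixation duration (s) and censoring flags.
The same chain is exposed as one call,
`run_behavior_pipeline("behavior.csv", "out/")`, which writes
`events.csv`, `features.csv`, `labels.csv`, `occupancy.csv`, a raster
figure and a manifest; `run_neural_pipeline()` does the analogous
composition for a neural recording. A thin command-line wrapper lives at
`inst/cli/sleepscope.R`.

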