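---
title: "Methods: sleep substates and neural dynamics in larval zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep substates and neural dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscope)
```

# Scope

Larval zebrafish sleep is behaviorally defined: locomotor speed below
0.5 mm/s sustained for at least one minute. Within such quiescent periods
the eyes are not necessarily still — they can produce conjugate saccades
whose rate and post-saccadic kinematics differ systematically across the
night and day. `sleepscope` implements the full analysis chain that turns
raw behavioral traces into a four-way partition of quiescence — three
eye-movement substates (QEM-1, QEM-2, QEM-3) plus quiescence without eye
movements (QNEM) — models how circadian time and ambient luminosity gate
those substates, and characterizes the brain-wide population dynamics of
QEM-1 (ramping activity over the course of each episode, state-space
trajectory entanglement, and decoding of relative time from population
activity).

No public recordings accompany the original study, so the package ships a
synthetic-data generator that emulates the statistical structure every
stage assumes. All tests and the reproduction script run on generator
output; what that does and does not demonstrate is discussed at the end.

# The behavioral chain

## Preprocessing and saccade detection

Left and right eye-angle traces (radians, uniform sampling; 50 Hz is the
reference rate) are detrended by subtracting a 200-s running mean. A
literal 200-s smoother applied as a low-pass would erase the saccades
themselves, so the long window is interpreted as a slow baseline that is
removed; this also makes the whole chain invariant to a constant offset
added to both eyes. A 1.5-s running median removes impulsive noise, and
the result is denoised with an exact one-dimensional total-variation
(fused-lasso) minimizer,
$$\hat\beta = \arg\min_\beta \tfrac12\sum_i (y_i-\beta_i)^2 +
\lambda \sum_i |\beta_{i+1}-\beta_i|, \qquad \lambda = 0.25,$$
computed by a direct non-iterative algorithm (the test suite checks it to
1e-6 against an independent box-constrained dual quadratic program). The
penalty is defined per sample at the trace's native rate. The residual
series (detrended minus denoised) is retained.

Saccade candidates are local maxima of the product of the two denoised
eye velocities (central differences) above 0.60 rad²/s² for the
multi-animal rig or 0.32 rad²/s² for the single-animal rig, pruned
greedily to a minimum inter-saccade interval of 1.5 s. A candidate is
accepted only if the interocular Pearson correlation in a 5-s window
around the peak exceeds 0.5 (rejecting vergence movements) and the
rolling 15-s mean absolute residual is below 0.45 rad (rejecting noisy
epochs); rejects carry a machine-readable reason.

## Kinematic scoring

Scoring works on the raw trace. Onset and offset bracket the velocity
peak at 10% of the peak velocity (the source analysis never defines
them; this is our choice, recorded here). Per eye, the baseline is the
median angle over 1 s pre-onset, the post-saccadic amplitude $A$ is the
offset angle minus baseline, the fixation duration runs from offset to
the first crossing of baseline $+\,0.33A$, and the decay slope is the
absolute OLS slope of the angle from offset up to (but not including)
the crossing sample. Events whose crossing is not reached before the
next accepted saccade or the end of the quiescent period are censored
there. Binocular values average the two eyes; peak speed is the maximum
central-difference velocity between onset and offset, reported in deg/s.

## Sleep periods, bins and substates

Sleep periods are maximal runs of 5-s rolling-average speed below
0.5 mm/s lasting at least 60 s. Each period is cut into 60-s bins; a
terminal remainder of at most 30 s merges into the preceding bin, a
remainder in (30, 60) s stands alone. Each bin yields three features:
saccade count (assignment by onset time), mean decay slope, and mean
fixation duration (censored fixations enter at their censored value).
Bins without saccades are QNEM by definition.

Saccade-containing bins are z-standardized and fitted with a
three-component diagonal-covariance Gaussian mixture: component $k$ is
initialized at +1 SD on feature $k$ (the "diagonally dominant"
initialization only makes sense on commensurate scales, which is why the
standardization comes first), variances are floored at 2e-5, and the
model order is selected by the sample-size-adjusted BIC,
$\mathrm{SABIC} = -2\log L + p\,\log\!\big((n+2)/24\big)$, over
$k = 1\ldots6$ with 10 EM restarts each. Restart solutions in which a
component is supported by fewer than $2(d+1)$ observations are treated
as near-singular spikes and discarded — without that guard the variance
floor lets one-point components inflate the likelihood and the order
selection drifts upward. Components map to substates by their dominant
feature: highest count mean is QEM-1, steepest decay-slope mean QEM-2,
longest fixation mean QEM-3; an ambiguous mapping raises an error. The
fitted mixture serializes to JSON so a reference fit can be frozen and
applied to other recordings (mirroring the cross-strain reuse of a single
classifier). Posterior ties break in component order QEM1 < QEM2 < QEM3.

# The gating model

Five-state probabilities (Wake and the four quiescent substates) are
modeled from three inputs at 1-min resolution: luminosity (0/1),
introduction day (1 on the day the animal entered the chamber), and
circadian time encoded as a 24-h cosine/sine pair phased by the clock
time at recording start. The architecture is a bottleneck multilayer
perceptron — dense encoder (24 units), scalar latent, dense decoder
(24 units), 5-unit softmax — with sigmoid activations by default (the
source material is internally inconsistent between sigmoid and ReLU;
both are available and the choice is stored in the model metadata). The
scalar latent forces all three inputs onto a single gating axis, which
is what makes the state-conditional latent distributions interpretable.

Training choices the source leaves open, fixed here: full-batch Adam at
learning rate 1e-3, at most 2000 epochs, early stopping on a training
loss plateau; cross-entropy loss on the per-time-step state
distribution. Summing the per-fish cross-entropies is algebraically
identical to a weighted cross-entropy against the empirical state
distribution per unique input row, so training cost is independent of
the number of fish. The cross-validated ensemble repeats a 5-fold split
over fish (20 repetitions by default, 100 models); held-out performance
is the Pearson correlation between predicted probabilities and the
fraction of held-out fish in each state, the observed fractions smoothed
with a 30-min moving average (window recorded in the ensemble object).

Ablations refit the full ensemble with one input time-shuffled (the
cosine/sine pair jointly), same seed and therefore the same folds, and
report the per-state drop in held-out correlation with a paired
signed-rank test across ensemble members. Causality of this readout is
tested on a construction in which ten random light schedules and their
complements drive the states: the across-fish lights average is then 0.5
at every clock time, so the circadian inputs carry exactly no
information and only the luminosity shuffle collapses performance. This
anti-phased design matters: with a single shared light schedule, the
circadian pair indexes absolute time and can memorize any time-locked
signal, and ablating luminosity does not collapse held-out performance
even though lights cause the behavior.

# Neural post-processing

Duplicate ROIs (centroids within 4 µm on all three axes and trace
correlation above 0.8 on co-observed samples) are grouped transitively
and only the best-covered member of each group is kept. Neurons observed
in fewer than half the samples are dropped. Photobleaching is corrected
by fitting $A e^{-t/\tau} + C$ (bounded least squares; profiled linear
coefficients over a τ grid, then a 1-D polish) and subtracting the
decaying part; the generator models bleaching as exactly this additive
decay so recovery is well-posed. Missing samples are linearly
interpolated for the analyses that need continuous traces.

Transient events: the baseline is the mean of samples below the rolling
10th percentile in a centered 45-s window; the noise SD is estimated
from the negative side of the baseline-subtracted trace as the RMS
deviation below its median (the below-median half is untouched by
positive transients and its RMS equals the noise SD for symmetric
noise — estimating instead from the sparse values below the already-low
baseline underestimates the noise several-fold and makes the threshold
fire continuously). Runs above mean + 2 SD lasting at least 2 s are
events; surviving events closer than 6 s merge into one. Filtering
before merging prevents isolated single-sample noise crossings from
chaining into spurious events. Per-state event rates divide event counts
by the duration of each state instance and average across instances;
neurons above 0.014 events/s in both wake and QEM-1 are flagged as
dual-active. On generator data the detector attains precision and recall
1.0 on event cells; fully silent cells still show a small false-positive
rate (~0.01 events/s), below the dual-activity operating threshold —
an intrinsic property of the thresholding rule worth knowing about.

# Encoding, ramps, enrichment

Each neuron is regressed on nine series: speed, roll, pitch, left and
right eye angle, turn bias (heading change convolved with a Gaussian of
σ = 8 min), a QEM-1 indicator, its within-period running integral
(reset at each period start, consistent with the per-period onset
kernel), and the period-onset impulse convolved with an exponential
kernel of time constant 1/15 of that period's duration. Fits use 10
contiguous time folds (OLS, tiny-ridge fallback for rank deficiency);
partial models shuffle one regressor group in time with identical folds,
preserving the parameter count; a group is significant when the drop in
mean fold R² exceeds twice the standard error of the full model's fold
R². On pure-noise neurons each flag fires in well under 15% of cases.

Ramp classification: every QEM-1 period of at least 3 min is a trial;
activity is linearly resampled to 1000 relative-time points, trials are
averaged, and the mean trace is peak-normalized (divided by its maximum
absolute value). Two bounded models are fitted by least squares — decay
$a\,e^{-\tilde t/b}+c$ and ramp-up $a\,(1-e^{-\tilde t/b})+c$ with
$0<a<1$, $0<b<2000$ — and the better R² names the class. Two choices
deserve comment. First, the printed exponent of the source reads
$e^{-1/(b\tilde t)}$; it is implemented as $e^{-\tilde t/b}$ (the
reported τ values only make sense that way), with the literal form
available behind `literal_exponent = TRUE` for comparison. Second,
min-max normalization of the mean trace was rejected: an exact
exponential decay min-max-normalized to [0, 1] requires amplitude
$a = 1/(1-e^{-1/b}) \ge 1$, which the printed bound forbids and which
biases $\hat b$ by ~50% on clean decay cells; peak normalization keeps
the bounds attainable and recovers generative time constants to well
under 10%.

Anatomical enrichment: for region $X$, $P(X)$ is the fraction of flagged
neurons among the region's $n_{tot}$ neurons; the null draws $n_{tot}$
neurons from the whole recording without replacement, 100 times, giving
$P_0(X)$; fold enrichment is $E(X) = P(X)/\overline{P_0(X)}$, and a
region is significant for one fish when $P(X) > P_0(X)$ in at least 95
of the 100 draws. (Resampling $n_{tot}$ rather than $n_{pos}$ neurons is
what makes $E(X) = 1$ under uniform labeling.) Across fish, a region
needs `ceiling(0.7 * n_fish)` individually significant fish — the
published criterion corresponds to 8 of 11.

# Population dynamics

State-restricted PCA averages each period's z-scored activity within ten
equal time-deciles, averages those neuron-by-10 matrices across periods,
computes principal components over the ten decile observations, and
projects the full recording on the top two components, with signs fixed
so PC1 increases with relative time. Entanglement of a period's 2-D
trajectory smooths each coordinate (Gaussian, σ = 12.5 s), represents
the trajectory as N−1 segments, counts intersecting segment pairs
(pairs sharing an endpoint excluded; counting unordered pairs once is
equivalent to halving a double-counted enumeration, and the production
counter is verified exactly against a brute-force O(N²) oracle), and
normalizes by the period duration. On generator data with ramping sleep
populations and unstructured wake activity, sleep trajectories are
reliably less entangled than wake trajectories.

Relative-time decoding z-scores activity within the state, bins each
eligible period (≥ 3 min) into 100 relative-time bins, and trains an
elastic net against a 0-to-1 ramp on all periods but one, rotating the
held-out period. Mixing values {0.1, 0.5, 0.9} and a log-spaced penalty
grid (1e-4 to 1) are chosen by inner leave-one-period-out validation on
the training periods. A scalar gain is then fitted on the pooled
predictions of all fish but one and applied to the held-out fish.
Controls: a within-state circular shift of each neuron by an independent
offset of at least 30 s (configurable) preserves autocorrelation while
destroying cross-neuron alignment; a behavior-only decoder applies the
identical protocol to speed, eye angles, roll and pitch. Neurons with
consistently signed median weights across fits classify as ramp-up
(positive) or ramp-down (negative).

# The generator: what it emulates, and what it does not

The generator is first-class, tested code; every downstream recovery
test compares against its event logs, never against re-derived values.

**State schedules** are semi-Markov draws whose per-phase occupancy
approaches configurable targets; lights follow a light/dark cycle,
constant light or dark, or seeded random switching (the random mode
exists so light-driven constructions can be decorrelated from circadian
time).

**Saccades.** Within a quiescent segment, each saccade event realizes
independently sampled kinematics: a flight built from equal angular
increments of $v\,\Delta t$ so the commanded peak speed is attained
exactly as a central-difference velocity; a ~0.16-s glissade down to a
post-saccadic step; a linear drift at the commanded decay slope for the
commanded fixation duration; and a brief (~3-sample) sub-saccadic dip
that carries the angle decisively across the 33% threshold at the
commanded fixation time, after which the eye holds until the next
saccade. The overshoot and the dip are both far shorter than the 1.5-s
median window, so the detection chain sees only the post-saccadic step,
while raw-trace scoring recovers peak speed, slope and fixation
essentially unbiased — this is what makes parameter recovery a
well-posed test of the full chain. Inter-saccade intervals are event
overhead + fixation + a rest interval whose mean is set so the mean
interval equals 60/rate; the regularity parameter interpolates between a
fixed rest (QEM-1, 0.8) and an exponential rest (QEM-2/3, 0.1) since the
source describes timing only as "regular" versus "irregular".
Positive kinematic quantities are drawn from moment-matched lognormals
(truncated normals would shift the mean of wide presets such as the
QEM-3 fixation duration). The post-saccadic step size is derived as
(slope × fixation + 2.3°)/0.67, floored at 7°, so the crossing outruns
angle noise (0.01 rad per eye by default) and the step stays above the
detector's product threshold after median filtering.

Two generator parameters are deliberate reconciliations rather than
published values. The flight amplitude preset (45 ± 5°, raised per
event when needed) exists because a saccade's measurable
central-difference peak speed at sample rate $f_s$ is bounded by
$A f_s/2$; at the 50-Hz reference rate the published ~849 deg/s peak
speed requires a two-sample excursion of ~34°, so a small-amplitude
preset would make the published speed unmeasurable by construction. And
the fixation process ends in a commanded crossing rather than at the
next saccade so that rate and fixation duration remain independently
controllable — in a real fish the 33% crossing is usually produced by
the next saccade itself, which ties the two quantities together.

**Wake** segments contain ~0.45-s swim bouts at ~1-s interbout
intervals with bout-coupled eye repositioning. **Neural populations**
contain QEM-1-suppressed cells, exponential ramp-down cells
(τ = 0.91 ± 0.03 in relative-time units, the published dorsal-raphe
value) and ramp-up cells (τ = 0.21 ± 0.01), boxcar event cells, and
noise cells, sampled at 2 volumes/s, with additive exponential
bleaching, a missing-sample mask, and signal-dependent Gaussian noise
(SD proportional to 0.25 + signal, emulating photon shot noise; with
signal-independent noise the published event-detection rule is not
operable, see above). **Head-ROI frames** render two dark ellipses
(semi-axes 0.16 × 0.09 mm, separation 0.24 mm from the midline) on a
noisy light background at 20 or 50 µm/px with a ground-truth sidecar.

What passing tests on generator data do show: the implementation of
every stage is internally correct, the published constants are applied
where the source states them, the full chain recovers known parameters
without bias at realistic noise, and the statistical rules are
calibrated (enrichment false positives near the nominal 5%, encoding
flags under 15% on noise). What they cannot show: robustness to real
tracking artifacts, non-stationary noise, template drift, genuinely
overlapping behavioral states, or any biological claim about real fish.
The published headline statistics (e.g., nighttime sleep fraction or the
whole-brain decoder's R² of 0.66) derive from recordings that are not
publicly available and are not reproduced here.

# Problem sizes and numerical choices

Default test and reproduction scales are chosen to run on a single CPU:
behavioral recovery uses 60–200 one-minute bins at 50 Hz (tests run
10 Hz where peak speed is not measured), the order-selection sweep uses
600 bins × 20 seeds, the gating-model causality check uses 20 synthetic
fish × 24 h at 1-min resolution with five-member ensembles, and the
decoding checks use 3 fish × 5 periods × 30 neurons. Tolerances: exact
primitives to 1e-6 against oracles; stochastic recoveries to 3 SE of the
generative spread; peak speed to 10% (finite sampling at 50 Hz);
eye-angle recovery to 2° over ±30° at both supported resolutions.
Degenerate inputs have defined behavior throughout: empty candidate
sets, zero-mass eye masks, unfitted or ambiguous mixtures, constant
predictors (correlation undefined, flagged NA), all-censored fixations,
and single-period decoding all raise errors or flags rather than
silently degrading.
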