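---
title: "Measuring human trace fear conditioning: models, preprocessing, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring human trace fear conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracefear)
```

## The measurement problem

In trace fear conditioning a conditioned stimulus (CS+) predicts an
aversive unconditioned stimulus (US) across a stimulus-free *trace
interval*; a control stimulus (CS-) predicts its absence. With long trace
intervals (15 s here) it is not obvious which psychophysiological channel
expresses the learned association, at what time within a trial, and how
trial-wise responses should be quantified so that the CS+/CS- difference
is measured with the least error. `tracefear` implements a complete
calibration pipeline for this question: a schedule generator for the trial
design, synthetic multi-channel recordings with known ground truth,
per-modality preprocessing chains, trial-wise quantification models, and
the inference layer used to compare candidate measures by *retrodictive
validity* — the effect size with which a measure separates CS+ from CS-,
which under fixed true learning is inversely related to measurement error.

The trial design is fixed throughout: acquisition presents 40 CS (20 CS+
at 100% reinforcement, 20 CS-), with a 2-s CS, 15-s trace interval and
~1-s electric US; recall, one week later, presents 30 unreinforced CS
(15/15) with a startle probe 13 s after CS offset, i.e. 2 s before the
expected US. The inter-trial interval is 30 s with a +/-2 s uniform
jitter, and at most three same-type CS occur consecutively.

```{r}
sched <- generate_schedule("recall", seed = 1)
sched
head(sched$trials, 3)
```

## Design choices in the schedule generator

The randomization algorithm behind the run-length constraint is not
dictated by the design, so the generator rejection-samples uniform
shuffles until the constraint holds; this is unbiased over all admissible
orders. The ITI jitter is uniform on [-2, +2] s. The incidental
digit-detection task performed during the ITI enters only as an event
timestamp (onset uniformly 5-10 s after the expected-US offset — in
recall sessions the expected-US anchor is used, since no US occurs and
the probe precedes it by 2 s); the task never enters any quantification.

US intensity calibration interpolates a rating-intensity curve at a
fraction (default 90%) of the "clearly painful" rating. Ratings are
occasionally non-monotone in practice; the implementation first replaces
a non-monotone curve by its isotonic regression, which leaves monotone
data untouched. No extrapolation is permitted.

## The synthetic cohort

No generative model of the recordings is given by the design, so the
generator's structural choices are the package's own. Each modality
produces per-trial true amplitudes

> amplitude = base x habituation(trial) x (1 + delta x [CS+]) x lognormal noise,

with exponential habituation `exp(-lambda (trial - 1))` (linear optional,
matching the two decay forms the analysis layer supports), a
multiplicative CS+ effect `delta` in CS- units, and lognormal
trial-to-trial variability (CV 0.3-0.4, the magnitude typical of startle
and electrodermal responses). Defaults (see `truth_params()`): EMG blink
amplitude 1 a.u. with lambda = 0.04/trial and delta = 0.3; skin
conductance bursts 0.3 / 0.4 / 0.8 uS (CS / trace / US components) with
delta = 0.5; pupil dilation 0.3 mm; US-locked bradycardia 8 ms;
respiration modulation 10%. Signal-to-noise ratios default to 10,
defined as mean response amplitude over noise SD on the scoring scale.

Noise models are deliberately simple: band-limited (50-470 Hz) Gaussian
carrier noise for EMG, AR(1) noise plus slow drift for the slow channels,
QRS-like impulse trains with optional slow heart-rate variability, and a
phase-continuous quasi-sinusoid for the respiration belt. Artifacts are
injected where the preprocessing chain must handle them: electric-shock
artifacts around the US in skin conductance, blinks / speed spikes / gaze
excursions beyond +/-5 degrees in the eyetracker channels, and ectopic
beats on request in the ECG.

What the generator does *not* emulate: real EMG spectra and
electrode-contact drift, electrodermal non-stationarity and spontaneous
fluctuations, biophysical ECG morphology, gaze dynamics beyond artifact
injection, and any dependence of noise on arousal. Passing parameter
recovery on these data therefore shows that the estimators invert their
own forward models under realistic noise magnitudes — a necessary
condition — but not that real recordings satisfy those forward models.

The sudomotor forward model is shared verbatim with the inverter: a burst
is a Gaussian bump (dispersion 0.3 s) convolved with the canonical
conductance kernel, so noiseless self-consistency is exact by
construction and noisy recovery measures estimator robustness only.

Every generator takes an explicit integer seed and is bit-reproducible;
sampling rates are arguments (digitizer defaults: EMG 2000 Hz, ECG
1000 Hz; slow channels are generated at 50-100 Hz).

## Preprocessing chains

Each chain follows the standard practice for its channel:

* **EMG, quality-control chain** (for GLM scoring): 4th-order Butterworth
  band-pass 50-470 Hz, 50 Hz notch, rectification, 4th-order low-pass
  with a 3-ms time constant. The time constant is interpreted by the
  usual smoothing convention `f_c = 1/(2 pi tau)` (~53.05 Hz). All stages
  are causal.
* **EMG, peak-scoring chain**: 4th-order 30 Hz high-pass, 50 Hz notch,
  rectification, centered 20-ms moving average.
* **Skin conductance**: causal first-order band-pass 0.0159-5 Hz,
  anti-aliased decimation to 10 Hz (4 Hz low-pass before subsampling),
  and masking of [US - 0.2 s, US + 1.6 s) on reinforced trials to remove
  the stimulation artifact. Masking is applied after filtering and before
  modeling; masked samples are excluded from model objectives and
  interpolated only for time-course averaging.
* **Pupil**: per-eye validity filtering in the order range, speed
  (16 x MAD of the two-sided dilation speed), edge margin (50 ms around
  gaps), trendline deviation (16 x MAD around a 300-ms moving-average
  trend), and minimum-island length (50 ms); eyes combined by averaging
  valid samples with single-eye fallback; samples with gaze outside
  +/-5 degrees marked missing; linear interpolation plus a 1-s moving
  average for time-course analysis. Trials with *strictly more than* 50%
  missing data between CS onset and the (expected) US are excluded. All
  thresholds are configuration keys (`pupil_filter_config()`). The
  device-unit-to-mm conversion is a pluggable affine map; synthetic data
  are generated in mm, so the default map is the identity.
* **ECG**: Pan-Tompkins-style QRS detection (5-15 Hz band-pass,
  derivative, squaring, 150-ms integration, adaptive thresholding with
  search-back, 200-ms refractory period; the adaptation constants follow
  the original description since only a "modified offline implementation"
  is specified). Because the integration stage flattens each beat into a
  plateau, detected positions are refined to the raw-signal R peak.
  Inter-beat intervals attach to the later beat; values outside
  600-1200 ms (50-100 bpm) are rejected; accepted IBIs are linearly
  interpolated to 10 Hz and band-passed at 0.015-0.5 Hz with zero-phase
  filtering. The band edges sit so close to DC on a 10 Hz grid that an
  8-pole transfer-function band-pass is numerically ill-conditioned, so
  the 4th-order response is realized as cascaded 2nd-order high- and
  low-pass sections.
* **Respiration**: inspiration onsets are positive-going zero crossings
  of the 0.04-1 Hz band-limited signal (the detrending operator is a
  design choice; only the detection behavior is prescribed); cycle
  amplitude is max - min within the cycle, assigned to the *next* cycle
  start, interpolated to 10 Hz, with no further filtering.

The 50 Hz notch is a constrained biquad with Q = 35 (no notch width is
prescribed; Q = 35 gives a -3 dB width of ~1.4 Hz). Every filter is
verified in the test suite against an independent direct-form difference
equation implementation.

## Trial-wise quantification

**Startle eyeblink (SEBR).** Peak scoring takes the maximum of the
rectified-smoothed envelope in the closed window 20-100 ms after probe
onset (window endpoints inclusive on the sample grid). GLM scoring
regresses the post-probe envelope on a canonical blink kernel (gamma
density peaking ~45 ms with ~25 ms width) over a grid of candidate onsets
(0-100 ms, 1-ms steps) with an intercept per trial segment, keeping the
slope at the best-fitting onset; the intercept is included because the
envelope is non-negative and has a non-zero noise floor.

**Skin conductance.** The three-burst trial model places CS- and
US-locked bursts at fixed 1-s latencies after their events (the latency
is fixed but its value is not prescribed; 1 s is the typical sudomotor
delay) and one free-latency burst in the trace window from 8 s after CS
offset to 1 s before (expected) US onset. On recall trials, where no US
occurs, the window is anchored at the nominal US time (CS offset + 15 s).
Inversion is deterministic bounded profile fitting: for each candidate
latency, amplitudes solve a non-negative least-squares problem with a
free intercept; the latency is searched on a 0.5-s grid and refined
locally. Fits whose latency clamps to a window bound, or that fail, are
flagged and retained (a configuration choice; dropping them is the
caller's decision). The trace-burst dispersion is fixed at 0.3 s. The
trapezoidal AUC from CS onset to the US timepoint is available as a
model-free summary.

**Pupil and heart period.** `glm_quantify()` implements single-trial (or
condition-wise) ordinary least squares with one regressor per response
function per trial, an intercept and a linear drift. Canonical kernels
ship as parametric defaults (pupil: gamma peaking ~2.5 s; heart period:
biphasic, bradycardic peak ~4 s), but the recommended route mirrors the
calibration logic: `estimate_rf_from_timecourse()` builds an empirical
response function from the trial-averaged time courses of a *training*
dataset (baseline-subtracted CS+ grand average, 1-s smoothing, truncation
to 0-17 s, peak normalization), records the source dataset identifier,
and `glm_quantify()` refuses to evaluate a fitted RF on its own training
dataset unless explicitly overridden. Validation of the kernels is by
parameter recovery, not kernel-shape fidelity. Heart period and
respiration anchor at the US (or would-be US at CS offset + 15 s on
recall trials); respiration uses early and late basis kernels
condition-wise.

**Normalization.** All amplitude estimates are divided by the subject's
CS- mean for the same session, modality, method, and component,
correcting multiplicative between-subject factors (electrode impedance,
anatomy). The normalized CS- mean is exactly 1; a subject whose CS- mean
is numerically zero is flagged and excluded from normalized analyses
rather than divided.

## Statistical layer

**Cluster-level permutation test.** Trial data 0-17 s after CS onset at
10 Hz (170 points) are averaged per condition and subject; a paired t
statistic is computed per timepoint. Clusters are maximal runs of
same-sign t values beyond a two-tailed point-wise threshold (default
alpha = .05 — the cluster-forming threshold is a configuration choice);
the cluster statistic is the mass (sum of |t|), and the null is the
maximum cluster mass when trial labels are permuted within each subject
(10,000 permutations by default), preserving per-subject condition
counts. P-values use the add-one estimator, which keeps the test valid
and p strictly positive. Subjects' observed-data degrees of freedom are
reused in permutations.

**Trial-averaging calibration.** For n = 1..15, the first n CS+ and
first n CS- trials per subject ("first n" counts within each condition
in presentation order) are averaged and compared by paired t-test, with
Cohen's d = mean difference / SD of differences and Hedges' g via the
small-sample correction. The 15 tests are deliberately not corrected for
multiple comparisons: the calibration selects by effect size, and its
guard is confirmation of only the selected n on an independent dataset
(`n_select`).

**Habituation and mixed models.** Startle and electrodermal responses
habituate independently of extinction, so condition effects are also
tested in a linear mixed model with a habituation-transformed trial
regressor: exponential decay for SEBR, linear for SCR. The decay rate is
fitted by ordinary least squares on a training dataset (grid search with
local refinement, amplitude profiled out) and then frozen for all
evaluation datasets. The model `amplitude ~ trialreg * condition` with
random intercept and trial slope per subject is fitted via `lme4`;
F tests use Satterthwaite denominator degrees of freedom by default
(configurable to residual df, since the exact df convention of any given
toolchain varies), with sum-to-zero condition coding and a centered
regressor so the condition test is the average condition effect. Singular
random-effects fits fall back to the random-intercept model with a
warning; AIC-based selection between the two structures is available and
is a training-dataset decision.

**Power planning.** `sample_size()` inverts exact noncentral-t power (no
normal approximation): paired design df = n - 1, ncp = d sqrt(n);
two-sample 1:1 design df = 2n - 2, ncp = d sqrt(n/2), reporting the
total across arms. A d = 0.44 retention effect needs 34 participants for
80% one-tailed power at alpha .05; halving that effect between two arms
(d = 0.22) needs 514 participants in total.

## Numerical choices and degenerate inputs

Zero-variance paired differences flag the calibration row rather than
producing an infinite t. Zero-variance timepoints in the permutation
test yield t = 0. NNLS amplitudes at 0 and trace latencies at their
bounds are legal solutions but flagged. The latency profile objective is
piecewise-smooth; the 0.5-s grid brackets the global minimum before
local refinement, and grid/refined candidates are compared so refinement
can never worsen the fit. Peak-scoring windows are inclusive on the
discrete grid; the US artifact mask is half-open ([-0.2, +1.6) s), which
gives exactly 18 samples on the 10 Hz grid.

## Problem sizes used in validation

The test suite validates parameter recovery on 200 synthetic subjects
per path (recall startle at 1000 Hz carrier sampling; acquisition skin
conductance at 50 Hz native sampling — both rates are documented
arguments, chosen here so the full suite stays fast while all band edges
remain well inside Nyquist), family-wise error control of the
permutation test on 500 null cohorts of 20 subjects x 30 trials x 170
timepoints at 1,000 permutations, and effect-size recovery of the
trial-averaging calibration on 500 simulated cohorts of 26 subjects with
the population effect matched to d = 0.44 at the full 15-trial average.
The calibration check evaluates d at the fixed full average rather than
at each cohort's selected maximum, because the selected maximum is
upward-biased by selection — the same reason the pipeline confirms a
selected average on an independent dataset.

## Known limitations

Synthetic validation cannot establish that real recordings follow the
forward models; the empirical response-function route exists precisely
because canonical kernels may misfit. The mixed model carries no random
condition slope, so when the CS+/CS- effect varies across subjects the
fixed-effect condition test is anti-conservative; its type-I error is
nominal only under the sharp null of no condition effect in any subject
(the paired t-test of subject means does not share this limitation). The permutation engine covers
1-D time courses only. Amplitude estimates carry no posterior
uncertainty. Tonic electrodermal decomposition is limited to the AUC
summary. Readers of the deposited experimental datasets need a
Matlab-container import adapter, which is out of scope for the core
package; all validation here is on synthetic data.
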