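---
title: "Detecting freezing of gait from wearable accelerometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from wearable accelerometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfog)
```

## The problem

Freezing of gait (FOG) is an episodic inability to progress the feet forward
despite the intention to walk, one of the most disabling motor symptoms of
Parkinson's disease. Detecting FOG automatically from body-worn inertial
sensors makes objective symptom quantification possible outside the lab and
is a prerequisite for on-demand cueing devices. The physiological signature
exploited throughout the FOG literature is spectral: normal stepping
concentrates acceleration power in the locomotor band (~0.5–3 Hz), while
trembling-type freezing shifts power into the 3–8 Hz "freeze band"; akinetic
freezing suppresses movement almost entirely.

`gaitfog` implements a complete detection pipeline over multichannel 3-axis
accelerometer recordings from up to seven body locations (lumbar, both upper
legs, both lower legs, both feet): signal conditioning, two-second epoching
with fraction-based labels, three classifier families behind one probability
interface, subject-grouped cross-validation with ROC/AUC model selection, an
operating threshold chosen by the geometric mean of sensitivity and
specificity, and a sensor-placement ablation.

## Signal conditioning

Three steps, in the order they are applied:

1. **Artifact rejection.** A sample is an artifact when any sensor's
   acceleration vector norm exceeds 100 m/s² or (when a gyroscope stream is
   present) its angular-velocity norm exceeds 20 rad/s. Detection runs on
   the *raw* signal — band-pass filtering would shrink spikes below
   threshold — and flagged samples are dilated by a ±0.25 s guard so filter
   ringing around a spike cannot leak into a window. The thresholds are
   scalar in the protocol; the package applies them to the per-sensor vector
   norm (a per-axis variant is available via `per_axis = TRUE`). Artifacts
   are masked rather than spliced out, so window timing stays aligned with
   the annotations; users comparing against deletion-based preprocessing
   should be aware of the difference.

2. **Zero-phase band-pass.** A third-order Butterworth band-pass with edges
   0.3 and 15 Hz removes drift while retaining both the locomotor and freeze
   bands. It is applied forward–backward (zero net phase, squared magnitude
   response) after odd-reflection padding of three filter lengths, the
   standard way to limit edge transients. The coefficients come from
   `signal::butter()`; the zero-phase application is done in-package so the
   padding scheme is pinned down and testable against the analytic transfer
   function.

3. **Rate standardization.** Recordings are 60 Hz (full-body protocols) or
   100 Hz (lower-body protocols); everything downstream runs at 60 Hz.
   100 Hz data is resampled by a delay-compensated polyphase 3/5 resampler
   (windowed-sinc anti-aliasing filter). The installed `signal::resample()`
   was measured to introduce a ~3-sample delay and ~0.8% passband ripple on
   a 5 Hz probe, which breaks the package's alignment and amplitude
   contracts, so the resampler is implemented here; a 5 Hz sinusoid survives
   with amplitude error below 0.1% and no time shift. The artifact mask is
   carried across rates by logical OR over every source sample overlapping
   an output sample. The gyroscope, used only for artifact detection, is
   dropped at this point: all models consume acceleration only.

## Windowing and labels

Cleaned recordings are cut into two-second windows (120 samples) with 75%
overlap, i.e. a 0.5 s hop. A window containing at least 25% FOG by time is
labeled positive (the boundary counts as FOG: 30 of 120 samples is
positive); a window with no FOG at all is negative; windows in between are
ambiguous and are discarded for training. At evaluation time the same rule
applies by default — symmetric semantics — with a `score_partial_as_neg`
option to score ambiguous windows as negatives instead, since the protocol
only fixes the training behavior. Windows touching any masked sample are
dropped whole rather than trimmed, keeping every input exactly 120 × C; they
never span trial boundaries. No amplitude normalization is applied: models
see band-passed raw acceleration.

Annotation intervals are half-open `[start, end)` seconds; sample *i* covers
`[i/fs, (i+1)/fs)` and takes its label from its midpoint, which keeps the
window FOG fraction within one sample period of the exact interval overlap.

## The classifier families

All three families train on identical window tensors and expose
`predict_proba()`, so the evaluation machinery is family-agnostic. No deep
learning framework is available in this stack, so the training cores are
purpose-built in C++ (RcppArmadillo): convolutions are im2col + BLAS
matrix products, and each family is a pure function of (data, config, seed)
— fixed initialization, fixed shuffling, no early stopping.

**CNN.** Three modules of convolution (kernel sizes 7, 3, 3; ReLU), max
pooling of size 2, and dropout 0.2, then flatten, dropout, a 10-unit ReLU
dense layer and one sigmoid unit. "Same" padding keeps the three
pool-by-two stages mapping 120 → 15 time steps for any kernel size. Trained
30 epochs with AdamW (learning rate 0.001, weight decay 0.001), batch 32,
class-weighted binary cross-entropy. Filter counts per block are not fixed
by the protocol; the package defaults to (16, 16, 16) and exposes them in
`cnn_config()`.

**InceptionTime.** An ensemble of five independently initialized inception
networks; the ensemble probability is the arithmetic mean of member
sigmoids. Each network stacks six inception modules — a 1×1 bottleneck,
three parallel convolutions with kernel sizes 2, 4, 8 (reduced from the
reference 10/20/40 because a 2 s window leaves little room for long
kernels), and a max-pool + 1×1 branch — concatenated, batch-normalized and
ReLU-activated, with a residual shortcut joining every third module, then
global average pooling into a sigmoid unit. Bottleneck and branch widths
default to the reference architecture's 32. Trained 20 epochs with Adam at
0.001, balanced class weights, no weight decay.

**MiniRocket.** A deterministic transform followed by a logistic head. The
kernel bank is all 84 two-valued kernels of length 9 (weights −1 with three
taps of +2, one kernel per choice of the three high taps). Each kernel is
dilated over an exponential schedule spanning the window, capped at 32
dilations per kernel; the 10,000-feature budget is spread equally, giving
`84 × floor(10000 / 84) = 9,996` features. Each feature is the proportion
of positive values (PPV) of the dilated convolution minus a bias; biases
are quantiles (a golden-ratio low-discrepancy sequence) of convolution
outputs computed on a seeded subsample of training windows, which makes the
features exactly invariant to rescaling the input amplitude. Multichannel
input is handled by summing a random channel subset per kernel–dilation
pair, subset sizes following a log-uniform law. Convolutions use "same"
zero padding at every dilation, so each kernel–dilation pair pools over the
full 120 samples. The head is a logistic regression on standardized
features, trained 10 epochs with Adam at 0.001 and class weights — 9,996
coefficients plus an intercept, the model's only trainable parameters.

## Evaluation protocol

Subjects — never windows — are the unit of splitting throughout, so no
person contributes to both sides of any comparison; the cross-validation
loop asserts this at window level.

- **80/20 hold-out split**, stratified by per-subject FOG-time percentage:
  quartile bins among subjects with any FOG, a separate bin for subjects
  with none, and a largest-remainder draw per bin whose fractional seats
  are assigned randomly (weighted by remainder) so no bin is systematically
  favored across seeds.
- **Five-fold subject-grouped CV** on the training pool; per-fold ROC
  curves are averaged vertically (TPR interpolated at 101 FPR points), with
  the population (ddof = 0) SD as the band. The summary AUC is the
  arithmetic mean of per-fold AUCs, not the area under the mean curve.
- **Model and configuration selection.** The family with the highest mean
  CV AUC is kept; the sensor ablation re-runs its CV over the five wearing
  configurations (seven sensors; six legs/feet; lower legs; lumbar; right
  foot) with the identical fold assignment for a paired comparison, and
  exact AUC ties break toward fewer sensors.
- **Threshold.** The operating point maximizes the geometric mean
  `sqrt(TPR × (1 − FPR))` over the selected configuration's pooled
  out-of-fold predictions, ties toward the larger threshold; predictions are
  positive at `p ≥ τ`. The frozen model and threshold are then scored once
  on the hold-out and unseen cohorts (sensitivity, specificity, precision,
  F-score; precision and F are reported as `NA` when nothing is predicted
  positive).

ROC points sit at every distinct score; the trapezoid AUC equals the
Mann–Whitney U statistic divided by `n_pos × n_neg`, which the test suite
verifies to 1e-12 against an independent pair-counting oracle (and against
pROC).

## The synthetic cohort generator

The generator exists because development and validation need data with the
statistical structure the analysis assumes. It emulates: a dominant
locomotor oscillation at a subject-specific step frequency (1–2.5 Hz, two
harmonics, left/right legs anti-phase, distal sensors moving more than the
lumbar sensor); trembling FOG episodes with a 3–8 Hz oscillation replacing
most of the locomotor power; an akinetic phenotype with near-silence;
0.25 s raised-cosine crossfades at transitions; additive Gaussian noise;
occasional super-threshold artifact spikes at Poisson times; and
between-subject variability in every parameter. Episodes follow an
alternating renewal process — exponential walking gaps, log-normal episode
durations (fixed log-sd 0.5, right-skewed as FOG durations are) — with the
walking mean set so the expected FOG-time fraction hits the subject's
target, drawn around 10.5% to match cohorts that spend roughly 9–12% of
walking time frozen. Mean episode length is drawn from 4–10 s, consistent
with cohort-level totals on the order of seven seconds per episode. Every
cohort is a pure function of its configuration and seed, down to the bytes
on disk.

What the generator does *not* emulate: gravity and orientation dynamics,
task geometry (turning, narrow passages), inter-rater annotation ambiguity,
heterogeneous hardware, or gait pathology beyond FOG itself. Passing the
learnability checks on this data therefore shows the pipeline's machinery
is sound — the labels are recoverable from the spectra the models see — not
that clinical-grade accuracy transfers to real cohorts; published AUCs on
clinical data (for example hold-out AUC near 0.72 against 0.86–0.90 in
training or unseen-task settings) are reference points, not reproduction
targets, because the underlying recordings are not publicly deposited.

A spectral baseline, `bandpower_score()` (logistic-squashed log ratio of
freeze-band to locomotor-band power), provides the floor any trained model
must beat; on trembling-phenotype cohorts it scores AUC > 0.9 by
construction of the generator.

## Numerical and design choices

- **Seeding.** One global seed fans out to per-stage seeds by hashing stage
  names (`derive_seed()`), so any stage can be rerun in isolation. All C++
  training uses its own Mersenne Twister stream; nothing depends on R's
  global RNG state, which is restored after every call.
- **Degenerate inputs.** Single-class training sets, mismatched channel
  layouts, schedules longer than a trial, overlapping annotation intervals,
  too-short filter inputs and sub-minimum cohorts all raise typed errors
  (`gaitfog_validation_error`, `gaitfog_format_error`, …) rather than
  propagating nonsense.
- **Ties.** Threshold ties break toward the larger threshold; ablation AUC
  ties toward fewer sensors; ROC thresholds are anchored at `Inf` so the
  curve always starts at (0, 0).
- **Batch-norm inference** uses running statistics (momentum 0.9), which is
  what makes ensemble predictions batch-size invariant.
- **Problem sizes.** The test suite exercises the full protocol at desk
  scale: cohorts of 5–20 subjects with 2–6 minute trials (the learnability
  check uses 20 subjects × 6 min = 2 h of signal, ~14,000 windows), chosen
  so the complete suite runs on one CPU in well under half an hour while
  every structural constant of the models stays at its protocol value. The
  end-to-end determinism check additionally shrinks training lengths
  (epochs, ensemble size, feature budget) through the config system — such
  overrides are echoed verbatim in the experiment report.

## Known limitations

- The recording format is package-specific CSV (self-describing, diffable);
  native motion-capture exports (e.g. MVNX) are out of scope, as is any
  orientation/frame processing — input is assumed sensor-local. A quaternion
  column set is reserved in the format but unimplemented.
- Episode-level (event-based) detection metrics, detection latency, and
  streaming inference are not implemented; evaluation is per-window.
- The CNN's total parameter count depends on per-block filter widths, which
  are configuration, not contract; reported totals for comparable
  three-block CNNs are therefore not reproduction targets. The MiniRocket
  feature count, by contrast, is fully determined by its configuration
  (9,996) and is asserted.
- The 0.5 s hop (75% overlap of 2 s windows) is applied uniformly to
  training and evaluation sets; protocols that epoch their test sets more
  finely will report different window counts for the same signal.
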