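---
title: "Estimating knee angle from surface EMG: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating knee angle from surface EMG: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgknee)
```

## The estimation problem

Surface electromyography (sEMG) measures the electrical activity of
contracting muscle and changes 20--300 ms *before* the resulting joint
motion, which makes it attractive as a control signal for wearable robotics:
an exoskeleton that can estimate the knee angle its wearer intends can assist
rather than fight them. `semgknee` implements a complete pipeline for
estimating the knee flexion angle over a gait cycle from multichannel sEMG
envelopes, with a recurrent encoder--decoder and Bahdanau attention at its
core, plus the evaluation and adaptation protocols that matter for real use:
attention-vs-baseline comparison, per-channel sensitivity, transfer to a new
wearer with a few personalization strides, and sequential adaptation during
use and across visits.

Because clinical gait recordings are rarely shareable, the package also
contains a first-class synthetic generator whose presets emulate the study
conditions of interest: healthy adolescent walking with eight thigh/shank
muscles, a six-channel "shared muscle" scenario for transfer learning, and a
cerebral-palsy crouch-gait variant with slow, variable strides and a poor
signal-to-noise ratio.

## Signal conditioning

Raw sEMG is conditioned per channel in five stages, in this order:

1. **Hampel filter** (window 20 samples per side, threshold 3 robust SDs):
   replaces a sample by its local median when it deviates from that median by
   more than `nsigma * 1.4826 * MAD` of its window. Windows are truncated at
   the signal edges. In a zero-MAD window any nonzero deviation is repaired
   -- an isolated spike amid identical samples is the clearest outlier there
   is -- while constant stretches pass unchanged and `nsigma = Inf` makes the
   filter the identity.
2. **Band-pass 50--190 Hz**, zero-phase Butterworth (order 4). Zero-phase
   (forward--backward) filtering is used everywhere because the EMG-to-angle
   lag is physiological information; a causal filter would add a spurious
   device lag. Both IIR stages use odd-reflection padding at the signal ends
   so filter transients decay inside the padding rather than corrupting the
   first seconds of data.
3. **Rectification** with a 50-sample sliding window: full-wave rectification
   (absolute value) followed by a centered 50-sample moving average. The
   coupling of rectification with a window length is read as
   smoothing-after-rectification, the standard construction.
4. **Consecutive peak and RMS envelope detectors** over a common window
   (default 150 samples): a sliding maximum followed by a sliding RMS, in
   that order. The window length is the one genuinely free parameter of the
   chain; it was calibrated on synthetic fixtures by maximizing rank
   agreement between the chain output and the generator's stored ground-truth
   envelopes, the same iterative-adjustment procedure one would use on real
   data. Shorter windows track narrow bursts more sharply but let
   carrier-amplitude noise through; 150 samples (150 ms at 1000 Hz) was the
   bias--variance optimum, with the weakest-gain narrow-burst channel (medial
   hamstrings) the limiting case at a rank correlation right around 0.9.
5. **Low-pass 6 Hz**, zero-phase Butterworth (order 4), the conventional
   linear-envelope cutoff. The final output is clamped at zero: a Butterworth
   can ring slightly below zero on a nonnegative envelope, and the chain's
   contract is a physical envelope.

All sliding windows truncate at the edges, so every stage preserves signal
length exactly.

## Gait segmentation and the model's input

Gait cycles span consecutive foot-contact events of one side (right by
default). Cycles shorter than 0.2 s or longer than 5 s are discarded as
event-detection artifacts. Each cycle's envelopes and angle are linearly
interpolated onto L = 100 equally spaced points (percent of gait cycle); a
fixed per-cycle length is forced by the segment structure below, and linear
interpolation is exact for the piecewise-linear trends involved.

Each normalized channel trace is tiled into five consecutive non-overlapping
20-sample segments. Segments are ordered time-major (all channels of the
first fifth of the cycle, then all channels of the second fifth, ...), so the
encoder walks the gait cycle chronologically: M = 40 segments for 8 muscles,
30 for 6. Train/test splitting is chronological (first 60% of strides train)
to avoid temporal leakage between adjacent strides; a seeded shuffled mode
exists. Per-channel min/max envelope bounds and the angle min/max are
computed on training strides only.

## The estimator

The encoder is a single-layer GRU (hidden size 100 by default) that consumes
one 20-sample segment per time step. The decoder is a second GRU that emits
the L = 100 angle samples one per step. At decoder step *t* the Bahdanau
attention scores every encoder state `h(j)`:

    score(j, t) = Va' tanh(Ua s(t-1) + Wa h(j))
    alpha(j, t) = softmax_j score(j, t)
    c(t)        = sum_j alpha(j, t) h(j)

and the decoder cell consumes `[y(t-1); c(t)]` with previous hidden state
`s(t-1)`; the output is a sigmoid of a linear projection of `s(t)`, on the
min--max-normalized angle scale, de-normalized to degrees with the training
bounds (so estimates always lie inside the training angle range). The
attention-free baseline is identical except `c(t)` is replaced by the final
encoder state `h(M)` at every step -- the classic encoder--decoder
bottleneck -- and differs by exactly the attention parameter count
(2H^2 + H). GRU cells follow the original convention
`h' = (1 - z) h + z n`. Weights are seeded uniform-Glorot; the decoder's
initial state is the final encoder state and y(0) = 0.

**Loss and training.** Full-batch ADAM (learning rate 1e-3) minimizes
element-wise binary cross-entropy between the sigmoid outputs and the
normalized angles; BCE on a [0,1]-normalized regression target is an
unconventional but workable choice (its gradient through the sigmoid is the
same `(prediction - target)` form as squared error on the logit scale), and
mean-squared error is available via `loss = "mse"`. Training stops when the
epoch's training RMSE (in degrees, computed from that epoch's forward pass)
drops below 15 degrees, or after 10,000 epochs.

**Free-running training.** The decoder is trained exactly as it is deployed:
it consumes its own previous prediction, and the gradient is carried back
through that fed-back output. The alternative -- teacher forcing during
training, free-running at inference -- was tested and rejected: on
constructed data a teacher-forced model reached ~3 degrees teacher-forced
test RMSE yet ~15 degrees free-running, even on its own training strides
(exposure bias). `teacher_forcing = TRUE` remains available.

All training is deterministic given the seed: identical seeds give
bit-identical parameters, and checkpoints (`save_gru_am()` /
`load_gru_am()`) restore estimators bit-exactly.

## Metrics

Per stride: RMSE in degrees; Pearson correlation (CC); SNR in dB, defined
literally as `10 log10(mean(theta^2) / mean(theta_hat^2))` -- the power ratio
of the measured to the estimated signal -- with an error-based alternative
(`method = "error"`, measured power over error power) behind a flag because
the literal form is atypical; and NRMSE, the RMSE divided by the measured
range. The convergence rate of a sequential run is the slope of the line
joining the first and last per-stride RMSE, in degrees per stride, with
strides as unit-spaced points.

## Protocols

* **Comparison** (`compare_models()`): both arms trained with matched seeds;
  the attention flag is the only difference. A caution discovered while
  validating the package: under the RMSE<15-degree stopping rule *both* arms
  terminate at the same training error on easy data, which pins both test
  errors near the threshold and makes the comparison degenerate. An
  architecture comparison should therefore disable the early stop and train
  both arms to the same fixed epoch budget (matched compute), which is what
  the package's own tests do.
* **Ablation** (`ablate_channels()`): each channel is removed in turn and the
  model retrained from scratch with the shared seed (weight reuse would
  entangle a channel's contribution with optimization history); channels are
  ranked by the test-RMSE increase over the full model. Meaningful rankings
  require models trained to convergence -- under-trained models turn the
  deltas into optimization noise.
* **Transfer** (`pretrain_transfer()` / `personalize()`): pretraining
  requires exactly the six-channel shared muscle set (TA, MG, SL, VL, RF,
  MH); personalization warm-starts on the subject's first 10 strides under
  the same termination rule.
* **Sequential learning** (`sequential_learn()`): prequential discipline --
  every stride is estimated and logged *before* it is ever trained on, so the
  logged per-stride RMSE is an honest measure of deployment performance.
  After every 3 strides the model is fine-tuned (warm start) on all strides
  seen so far, capped at 50 epochs per update or the RMSE criterion,
  whichever comes first; a sliding-window buffer is available via config.
  `progressive_visits()` chains runs across visits with model state carried
  over.

## The synthetic generator

Per stride, a gait speed and step length are drawn from the preset's
spatiotemporal distribution (healthy: 0.91 +/- 0.04 m/s, 0.52 +/- 0.02 m;
crouch-gait visits V1--V3: 0.14, 0.37, 0.52 m/s) and the stride duration is
2 x step / speed. The knee-angle cycle template is a baseline flexion offset
plus wrapped Gaussian stance- and swing-flexion waves (healthy: ~5 degrees
baseline, 20-degree stance wave at 15% cycle, 62-degree swing peak at 72%;
crouch: 32-degree baseline, reduced range). Channel envelopes are wrapped
Gaussian activation bursts at standard gait timings (TA at contact and
through swing, MG/SL late stance, RF/VL loading response and pre-swing, MH
terminal swing) with per-stride lognormal-like gain jitter. Raw EMG is the
envelope amplitude-modulating a band-limited (60--180 Hz) zero-mean carrier
plus a white noise floor, so the 50--190 Hz conditioning chain is exercised
meaningfully.

The angle is the template plus a fixed linear map of *lagged* (40 ms)
per-channel envelope deviations, so the EMG genuinely precedes and informs
the angle, and the coupling weights give the knee flexors/extensors (RF, MG,
TA, VL) the largest influence -- providing ground truth for sensitivity
analyses. Ground-truth envelopes, gains, weights and noise powers are stored
with every trial. `cp_degrade()` re-synthesizes a trial with the
envelope-to-noise power ratio scaled by a factor and variability inflated,
with identity factors reproducing the trial bit-exactly.

What the generator does *not* emulate: electrode lift-off and motion
artifacts, crosstalk between channels, spasticity-driven co-contraction,
fatigue drift within a session, or marker-based kinematic noise. Passing
tests on synthetic data therefore demonstrate that the pipeline and
estimator are correctly implemented and can learn an EMG-to-angle mapping of
realistic structure -- not that any particular clinical accuracy would be
achieved on real recordings.

## Problem sizes used by the test-suite experiments

The package's own experiments are run at desk scale, chosen as the smallest
sizes at which each effect is cleanly measurable: the training-termination
run uses the full 60-stride healthy dataset at hidden size 100 with the
low-noise condition (noise scale 0.1); the attention-vs-baseline comparison
uses 24 strides, hidden 32, five seeds, and a fixed 150-epoch budget; the
ablation ground truth uses 20 strides with RF-dominant coupling, hidden 24,
and a shared seed; sequential-learning runs use 30-stride streams with
3-stride update cycles. The structural checks (segment counts, update-cycle
counts, metric oracles) are size-independent.

## Known limitations

* The BCE loss is kept as the default for fidelity; MSE often converges
  slightly faster on this task.
* The decoder emits 100 scalar steps per cycle; per-segment (5-step) output
  granularity is not implemented.
* Both limbs are never pooled; the pipeline follows the dominant-side
  convention.
* The stopping rule reads the RMSE of the epoch's own forward pass (i.e.
  parameters as of the epoch start), avoiding a second forward per epoch;
  the reported terminal RMSE is therefore conservative by at most one
  update step.
* `signal::filtfilt` provides no initial-condition matching; the
  odd-reflection padding above is the standard remedy but very long
  low-frequency transients (cutoffs well below 1 Hz) would need longer
  padding than the default three time constants.
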