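---
title: "Recognizing cigarette smoking from forearm sEMG and IMU signals"
author: "smokescreen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing cigarette smoking from forearm sEMG and IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokescreen)
```

## The problem

A forearm band records eight surface-electromyography (sEMG) channels
together with a three-axis accelerometer and gyroscope, all at 200 Hz with
sEMG quantized to 8 bits. The task is person-independent recognition of
cigarette smoking: classify every 10-second window of the multichannel
stream as smoking or non-smoking, training on some people and testing on a
person the model has never seen (leave-one-subject-out, LOSO). Smoking is
visible in both modalities — the hand-to-mouth puff gesture rotates the
forearm (IMU) and recruits wrist/finger muscles (sEMG) — but so are
confounders such as eating, which shares the gross kinematics. The central
scientific question the pipeline addresses is whether sEMG adds information
over the inertial sensors, alone or fused.

The original validation study this package's method derives from (16
smokers, 25 h, 64 smoking events) was never deposited, so the package ships
a synthetic cohort generator that emulates the study's structure; every
stage is exercised end to end on synthetic data.

## Pipeline

### Windowing and labeling

The stream is cut into 10 s windows sliding by 5 s
(`windowing_config()`); a recording of duration $T$ yields
$\lfloor (T - W)/S \rfloor + 1$ windows and trailing partial windows are
dropped. A window is labeled smoking when at least a fraction
`min_overlap_fraction` (default 0.5) of it lies inside the union of
smoking-class activity intervals. The original study's description of the rule
("corresponded to a smoking session") does not quantify the overlap; the
0.5 default avoids labeling windows dominated by non-smoking content at
session boundaries, and a threshold approaching 0 recovers the "any
overlap" reading. All four smoking activities of the protocol (smoking
while sitting, while walking and talking, while talking and sitting, while
walking) count as smoking.

### Spectrogram images

Each selected channel of a window is transformed with a short-time Fourier
transform — 512-point FFT over 256-sample Hamming frames with 95% overlap
(hop `round(256 * 0.05) = 13`) — log-scaled to dB with a −120 dB floor, and
conformed to a fixed 256 × 112 (frequency × time) image; channels stack
along the third axis. The two statements in the original analysis recipe are mutually
inconsistent: the stated STFT parameters give 135 frames on a 2000-sample
window, not 112. We therefore honor the parameters for analysis and treat
the stated 256 × 112 as the tensor contract: the redundant one-sided bin is
dropped (257 → 256) and the time axis is resampled to 112 bins by linear
interpolation between frame centers (`conform_shape()`). IMU channels pass
through the identical transform and stack into the same tensor for the
fused configuration; the original work does not say whether it treated them
differently.

Per-channel standardization (z-score over all bins of a channel) is applied
after log scaling. Its statistics are fitted on training folds only and
carried to the held-out subject — a LOSO purity requirement that the test
suite audits explicitly.

### CNN-LSTM classifier

`build_model()` constructs three convolutional blocks — convolution,
batch normalization, rectifier, 2 × 2 max-pool — with feature-map depths
128/64/32 and filter spatial dimensions equal to half of each layer's own
input dimensions (floored, minimum 1), followed by a 32-unit fully
connected feature layer with 0.5 dropout, two LSTM layers of cell size 64,
and a single sigmoid output. Training uses Adam with learning rate
$10^{-2}$, mini-batches of 64 and five epochs.

Several points of the original description are under-specified and were
decided here; each remains configurable:

* **"Five iterations"** is read as five epochs — five mini-batch steps could
  not traverse a study-sized window set even once.
* **LSTM sequences.** The recurrent layers classify "temporal dynamics of
  the extracted 32 features", which are per-window; we feed overlapping
  runs of 6 consecutive windows of the same recording (about 35 s of
  context at the 5 s slide), one run ending at every window, so each window
  receives exactly one prediction. Runs at a recording start are left-padded
  by repeating the first window and flagged.
* **Output and loss.** A single sigmoid unit with binary cross-entropy, the
  canonical choice for a binary task described only as "one output layer".
* **Pooling edge.** Max-pooling keeps a trailing partial neighborhood
  (pooled size $\lceil d/2 \rceil$, `pool_edge = "ceil"`). The neighborhoods
  remain non-overlapping, and the stack stays well-defined for images of any
  size; with the strict floor reading small inputs collapse to zero
  dimensions (the `"floor"` mode is available and then raises the
  configuration error naming the offending block).
* **Gradient clipping.** The specified learning rate is large for this
  depth, so the trainer clips the global gradient norm at 5 by default
  (`max_grad_norm`); this is a stability guard, not a tuned quantity.

The implementation is the package's own: im2col + GEMM convolutions with
hand-written batch-norm, pooling and LSTM backward passes, the hot loops in
compiled code (`src/conv.cpp`) and the small recurrent head in R over BLAS.
Analytic gradients are verified against central finite differences in the
test suite. Seeded runs are bit-reproducible within one environment; exact
cross-environment bit identity is not promised (BLAS summation order may
differ), which is why stochastic checks use tolerances.

### Channel selection

`sfs_select()` wraps the classifier in sequential forward selection over
sEMG channels: each step appends the candidate that maximizes the criterion
(F1 by default, accuracy available — the original description says "accuracy" but
reports F1-centric results, so both are supported), with ties broken toward
the lowest channel index. Evaluating every candidate under full LOSO is
quadratic in subjects × channels, so the inner evaluation defaults to a
grouped subject-wise holdout; full LOSO remains available. The classifier
inside the wrapper is pluggable: the CNN-LSTM itself (typically at reduced
epochs) or a fast logistic-regression surrogate on per-channel band-power
summaries, which responds to the same amplitude-modulation signal and is
what the tests use. `best_subset()` returns the earliest maximal prefix of
the trace.

### Evaluation

`run_experiment()` runs LOSO per sensor configuration (all-sEMG, selected
sEMG, IMU, IMU+sEMG), accumulates per-fold confusion matrices, and reports
metrics under **both** conventions: micro (from accumulated counts) and
macro (mean of per-fold metrics). Both are reported because the published
reference table is not arithmetically consistent with a single convention —
its all-8-channel F1 prints 0.70 while the accumulated counts give 0.73,
and the fused F1 prints 0.84 against a computed 0.8476.
`check_published_metrics()` recomputes every printed value from the counts
and flags the mismatches rather than forcing them. Paired comparisons
between configurations use McNemar's test on the identical pooled held-out
windows; the default is the exact two-sided binomial form, valid at any
discordant count (the continuity-corrected chi-square variant is available
and agrees with the exact form in the moderate-count regime; for extremely
lopsided discordant pairs the chi-square approximation is poor, which is
precisely why the exact form is the default). The decision threshold is
fixed at 0.5 throughout; no operating-point tuning.

## The synthetic cohort generator

`generate_cohort()` emulates the validation study's structure:

* **Protocol.** Ten ordered activities per subject (reading, two walking
  speeds, resting, phone call, eating, four smoking sessions). Non-smoking,
  non-eating activities are capped at 5 min. The default protocol uses
  267 s smoking sessions — the study's 4.75 h over 64 events — and 4
  sessions per subject, matching 64 events over 16 subjects.
* **Puffing.** Smoking sessions contain puff trains: durations uniform on
  2–4 s, gaps uniform on 20–40 s. The source reports only totals, not puff
  timing, so these are plausible smoking-topography values, chosen once.
  Eating contains analogous "bite" trains (1.5–3 s every 8–15 s).
* **sEMG model.** Channel $c$ is zero-mean Gaussian noise band-passed to
  20–95 Hz (a realistic surface-EMG energy band under the device's 100 Hz
  Nyquist), amplitude-modulated by
  $\sigma_0 (1 + (g-1)\, w_{a c}\, e(t))$ where $\sigma_0$ is the resting
  noise SD, $g$ the burst gain, $w_{ac}$ the activity-by-channel activation
  weight and $e(t)$ a raised-cosine gesture envelope; then rounded and
  clipped to the signed 8-bit range. Smoking recruits mainly channels 4–6,
  eating a different group — the two hand-to-mouth confounders are
  separable by sEMG but not by gross kinematics.
* **IMU model.** Gravity rotated through a smooth forearm-pitch excursion
  during hand-to-mouth gestures, gait oscillation during walking
  activities, and measurement noise; the gyroscope is the pitch rate plus
  the same disturbances.
* **Subject variability.** Activation weights and gesture amplitudes get
  per-subject multiplicative log-normal jitter, which is what makes LOSO
  genuinely harder than a random split.

Everything is a pure function of (protocol, parameters, seed); per-subject
sub-seeds derive deterministically from the master seed.

What the generator does **not** emulate: electrode lift and motion
artifacts, real sEMG spectral nonstationarity, magnetometer data,
inter-device variation, or free-living behavior. Passing the end-to-end
tests therefore demonstrates that the pipeline is implemented correctly and
can learn the intended signal structure — not that the reported real-data
accuracies would be reproduced; those require the undeposited recordings.
One visible consequence: on the synthetic easy preset the selected-sEMG
configuration is cleaner than the IMU configuration (the reverse of the
original study's ordering), because synthetic sEMG bursts are
high-contrast; the fusion property — the fused configuration at least
matching the best single modality — is the behavior the experiments check.

## Experiment scales and numerical choices

The learning-sanity experiment uses the package's *easy preset*:
8 subjects × 20 min, burst gain 8, dense puffing (8–14 s gaps so nearly
every smoking window overlaps a puff), low baseline noise — and the
*reduced spectrogram preset* (`reduced_spectrogram_config()`): a 16-point
FFT over 16-sample Hamming frames at 50% overlap conformed to 8 × 8
images, i.e. 12.5 Hz frequency resolution over 0–87.5 Hz. For
amplitude-modulated band-noise this resolution retains the discriminative
burst structure while shrinking classifier cost by roughly four orders of
magnitude relative to full-size 256 × 112 images, whose first-layer
128 × 56 filters make the published architecture extremely expensive at
any scale. The full-size configuration remains the default contract and is
shape-tested; the reduced preset is the package's chosen scale for training
experiments. LOSO over 8 subjects × 3 sensor configurations × 3 seeds is
then a 72-fold training job that completes in minutes on one CPU.

Other numerical choices: dB floor −120; batch-norm $\epsilon = 10^{-5}$,
running-statistics momentum 0.1; He-normal initialization for convolutional
and dense weights, uniform Glorot for LSTM weights with forget-gate bias 1;
standardizer guards against zero spread by flooring the SD at $10^{-8}$;
pooling ties resolve to the first neighborhood element; SFS ties to the
lowest channel index; interval arithmetic treats windows as half-open.

## Known limitations

* Synthetic-only validation; see above for what that does and does not show.
* The LSTM sequence construction is an interpretation of an under-specified
  description; alternatives (e.g. intra-window time-bin sequences) are not
  implemented.
* The published per-configuration confusion counts cannot be regenerated,
  only their arithmetic checked.
* Exact reproduction across BLAS implementations is not guaranteed;
  determinism is per-environment.
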