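---
title: "DCAMNet: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DCAMNet: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Driver fatigue changes the EEG in well-characterized but
subject-dependent ways: frontal theta (4–8 Hz) power rises, alpha
(8–13 Hz) power rises before suppressing, and beta (13–30 Hz) activity
falls as alertness degrades. The exact frequencies, electrodes and time
courses differ across people, so a classifier with a fixed spectral
filter tuned on one set of drivers transfers poorly to a new driver.
`dcamnet` implements a compact convolutional detector whose spectral
filters are chosen *per sample*: a squeeze-and-excitation (SE) branch
inspects the band-energy profile of each epoch and mixes K basis kernels
accordingly. This vignette explains the model, the labeling schemes, the
evaluation protocols, the synthetic generator, and the numerical
decisions that are not forced by the mathematics.

## Signal path

An epoch is a channels-by-time matrix `x` (microvolts). Preprocessing is
a fourth-order zero-phase Butterworth bandpass (0.5–45 Hz) followed by
segmentation into non-overlapping epochs, either contiguous or
time-locked to the window immediately preceding a behavioral event. No
re-referencing and no artifact rejection are applied; the model is meant
to work on minimally processed signals.

A nine-band filter bank (delta 0.5–4, theta 4–8, alpha1 8–10, alpha2
10–13, beta1 13–20, beta2 20–30, gamma1 30–36, gamma2 36–42, broadband
0.5–45 Hz) expands each epoch into a tensor `xfb` of shape
`(Nb = 9, C, T)`. Band index 1 is delta and index 9 is broadband; this
ordering is fixed and used by the masking analysis. The bank uses the
same filter family and order as preprocessing, for uniformity.

## The network

**Dynamic convolution.** K parallel kernels, each of shape
`(N, Nb, 1, L)`, act along the time axis only (channel mixing is
deferred to the next block). For each sample, global average pooling
compresses `xfb` over channels and time to a band descriptor `g` of
length Nb; two linear maps with a ReLU bottleneck
(`z = W2 relu(W1 g)`, bottleneck `max(1, floor(Nb/r))`) produce K
logits, and a temperature-scaled softmax yields attention weights `pi`
on the simplex. The effective kernel and bias are the `pi`-weighted
convex combinations of the basis kernels; convolution, batch
normalization and ELU give `xtf` of shape `(N, C, T1)`. Smaller
temperatures concentrate `pi` on fewer kernels; the package exposes
`tau_d` with default 1.

**Spatial convolution.** `m` filters of shape `(C, 1)` contract the
`(N, C)` axes at every time point (no bias), followed by batch
normalization and ELU, yielding `m` single-channel series.

**Temporal attention.** Each series is split into `n = floor(T1/w)`
non-overlapping windows; the population variance (divisor `w`) of each
window is a local energy descriptor. A single `h x n` matrix `U`,
shared across the `m/h` channel groups, is normalized row-wise with a
softmax over the window axis and used to take a convex combination of
each channel's window variances. The result is an `m`-vector passed
through dropout (rate 0.5) to a bias-free linear classifier with
softmax.

Defaults (`K = 4`, `L = 64`, `N = 16`, `r = 4`, `m = 16`, `w = 25`,
`h = 4`, `Nc = 2`, Adam with learning rate 1e-3, weight decay 1e-4,
halving every 50 epochs, batch 64, early stopping with patience 30 on a
10% stratified validation carve-out) reproduce the reference
configuration of the architecture.

## Labeling schemes

**Reaction time (driving deviations).** For event `i`, the local
reaction time is `LRT(i) = Act(i) - Dep(i)`; the global reaction time
`GRT(i)` is the mean LRT over prior events whose onsets fall within the
preceding 90 s (undefined when fewer than two qualify). With `ART` the
95th percentile of all LRTs, an event is fatigued when both LRT and GRT
exceed `2.5 ART`, alert when both are below `1.5 ART`, and discarded
otherwise. Decisions taken here, because the rule's source leaves them
open: events with undefined GRT are discarded (the rule needs both
conditions); boundary values exactly at `1.5 ART` or `2.5 ART` are
discarded (the inequalities are strict); the percentile uses linear
interpolation between order statistics (`stats::quantile` type 7,
configurable); `ART` is computed over the pooled dataset by default,
per-session optionally. Subjects are retained only with at least 50
labeled segments per class.

**PERCLOS (eye tracking).** Per 4 s epoch, PERCLOS is the closure time
divided by the observable interval (blink + fixation + saccade +
closure); epochs whose observable interval is zero are left unlabeled.
The threshold rule is strict: fatigued iff PERCLOS > 0.5.

## Evaluation protocols

The *subject-mixed* protocol splits epochs stratified by class (70/30 by
default), so one subject's epochs can appear on both sides; it is an
upper bound, reported as such. The *LOSO* protocol holds each subject
out in turn. In both, the early-stopping validation set is carved out of
the training portion only — never from test, and in LOSO never from the
held-out subject. Ties at the decision threshold go to the alert class
(deterministic argmax).

Fold aggregation reports three quantities explicitly, because they
genuinely differ: the unweighted mean (with sd and a
normal-approximation 95% CI, `mean ± 1.96 sd / sqrt(n)`), the summed
aggregate confusion matrix, and the accuracy recomputed from that
matrix (the sample-weighted mean). Paired fold comparisons use the
two-sided paired t-test, the Wilcoxon signed-rank test (exact null for
n ≤ 25 when the differences are tie-free, normal approximation with
continuity correction otherwise) and paired Cohen's d
(`mean(diff)/sd(diff)`); degenerate difference vectors are flagged
rather than reported as spurious statistics.

## Training engine

No deep-learning framework is involved: the forward and backward passes
are written in vectorized R, with the convolution expressed as a
per-sample im2col gather followed by BLAS matrix products, and gradients
derived analytically for every block (verified against finite
differences in the test suite). Adam follows the standard
bias-corrected update with L2 weight decay added to the gradient of
every parameter. Batch normalization uses population batch statistics
in training, running statistics (momentum 0.1) in evaluation, matching
common deep-learning practice; single-sample inference therefore relies
on the running statistics accumulated during training. Weight
initialization is fan-in-scaled uniform, `U(-1/sqrt(fan_in),
+1/sqrt(fan_in))`, biases zero, fully seeded; a training run is
bit-reproducible given its seed.

## Numerical choices

* **Zero-phase filtering.** "Fourth-order zero-phase Butterworth" is
  realized as a fourth-order design applied forward and backward
  (effective magnitude order eight, zero phase). Each pass starts from
  the steady state of its first padded sample, and the odd-reflection
  padding is sized from the slowest pole of the design (about six time
  constants, at least three times the effective order, capped at the
  signal length minus one). A fixed short padding is not enough here:
  the 0.5 Hz edge has poles of radius ~0.994 at 200 Hz, whose
  transients persist for hundreds of samples. With this scheme DC input
  is suppressed exactly and pass-band sinusoids keep the designed
  magnitude away from the epoch edges; epochs much shorter than the low
  edge's time constant retain some edge transient.
* **'Same' padding for the dynamic convolution** (stride 1, zero
  padding), so `T1 = T` and window counts stay clean (e.g. 800/25 = 32
  windows); 'valid' is available behind a config flag.
* **SE bottleneck** `Nb/r = 9/4` is not an integer; it is floored with
  a minimum of 1, so an r sweep over {2, 4, 8} uses bottlenecks
  {4, 2, 1}.
* **Attention normalization.** The temporal attention matrix is
  softmax-normalized row-wise before the weighted sum, making each
  output a convex combination of window variances; a flag disables the
  normalization for the raw-weights variant.
* **Bias-free spatial and classifier layers**, matching the layer-table
  parameter accounting (`m*N*C` and `Nc*m`). The parameter counter
  reports both that layer-table total and a full count including SE and
  batch-norm affine parameters. The counter is formula-driven;
  externally printed model totals that disagree with their own layer
  formulas are not reproduced.
* **Coordinates.** Time windows are half-open `[start, end)` in
  seconds; sample indices are 0-based at the interface (R's 1-based
  indexing is internal). Samples are microvolts.

## Ablation variants

`static_K1` replaces the dynamic convolution by one static kernel (no
SE branch); `no_spatial` removes the spatial block and mean-pools over
channels before the temporal block; `no_temporal` replaces temporal
attention by global average pooling over time; `minimal` keeps only the
static convolution (global average pooling over channels and time) and
the classifier. Band masking zeroes all but a selected set of
filter-bank slices and pushes the masked tensors through an
already-trained network without retraining; channel ablation removes
electrodes from the dataset and retrains at the reduced `C`.

## Synthetic generator

Each epoch is `1/f^gamma` background noise (default exponent 1,
synthesized in the frequency domain) plus three amplitude-modulated
narrowband oscillations: theta centered at 6 Hz, alpha at a per-subject
individual peak drawn in 8.5–12.5 Hz, beta at 20 Hz. Narrowband
processes rather than pure sinusoids avoid degenerate filter-bank
behavior. Fatigued epochs raise theta and alpha power and suppress beta
by configured dB effects (defaults +3, +2, −2 dB); every subject also
carries its own band offsets (up to ±2 dB), alpha peak and noise scale,
which creates the between-subject variability that makes LOSO genuinely
harder than the mixed protocol. The individual alpha peak range spans
the alpha1/alpha2 boundary deliberately: real individual alpha
frequency varies over roughly this range, and it is exactly the kind of
spectral variability per-sample kernel adaptation is meant to absorb.
Deviation sessions draw event onsets 5–15 s apart with tight alert
(0.5–1.0 s) and inflated fatigued (3.5–5.0 s) reaction times, returning
the generator's intent per event; eye-tracking epochs are built so the
expected PERCLOS equals a target trajectory. Everything is seeded and
bit-reproducible.

What the generator does *not* emulate: volume conduction and realistic
spatial topographies (channels are exchangeable up to noise), ocular and
muscle artifacts, non-stationary drift within a session, and label
noise. Passing tests on this data shows the pipeline is correct and
that the architecture can exploit band-power structure; it does not
certify performance on real recordings.

## Desk-scale experiments

The packaged reference experiments are sized to finish in minutes on one
CPU and are used by the test suite and the reproduction script:

* `desk_mixed_experiment()`: 4 subjects × 30 epochs/class, 6 channels,
  2 s epochs at 100 Hz, strong effects (+6/+4/−4 dB), model
  `K=4, N=8, L=16, m=8, w=25, h=4`, batch 32, up to 100 epochs with
  patience 20. The long training matters for the masking analysis: an
  under-trained network, probed with single-band tensors whose scale is
  far below the batch-norm statistics, saturates the ELUs and predicts
  one class everywhere.
* `desk_loso_experiment()`: 5 subjects × 16 epochs/class, 5 channels,
  1.5 s epochs, moderate effects (+4/+3/−3 dB) with per-subject
  offsets, model `K=4, N=8, L=12, m=8`, learning rate 2e-3 for 40
  epochs (patience 10), the protocol's five fixed training seeds
  (0–4), comparing the full model against `static_K1`. Five subjects
  is a deliberate floor: with two or three training subjects per fold
  the held-out subject's spectral profile lies outside the training
  distribution and per-sample adaptation cannot help (an extrapolation
  regime); the directional advantage of dynamic convolution needs the
  held-out profile to be interpolatable from the training subjects.
  Even so, the contrast at this scale is small relative to its
  seed-to-seed variability — per-seed differences span several points
  in both directions — so only the mean over the five seeds is
  interpreted, and only directionally.

## Known limitations

The EDF and HDF5 container formats are not read by this build; the
array-dump interchange format is CSV plus a JSON sidecar. Training is
CPU-bound R and sized for desk-scale experiments, not for full-scale
benchmark replication. The LOSO advantage of dynamic convolution at
desk scale is directional and small; demonstrating the full published
margin requires the real multi-subject recordings, which are outside
the scope of this package's tests.
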