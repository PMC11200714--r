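---
title: "Decoding SSVEP from few-channel EEG with attention-augmented complex-spectrum CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding SSVEP from few-channel EEG with attention-augmented complex-spectrum CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The decoding problem

A steady-state visual evoked potential (SSVEP) speller presents a grid of
flickering targets; attending one of them entrains occipital EEG at the
flicker frequency and its harmonics. With joint frequency-phase modulation
(JFPM), target (i, j) of the grid flickers at

\[ f_{i,j} = a_i\, i + a_j\, j + a_0 \qquad
   \varphi_{i,j} = (b_i\, i + b_j\, j + b_0)\,\pi \]

so every target owns a unique (frequency, phase) pair. The two built-in
layouts are a 40-target speller (`build_layout("dataset1_40class")`,
`f = 2i + 0.2j + 5.8` Hz, `phi = (5i + 0.5j - 5.5)pi`, 8.0-15.8 Hz) and the
public 12-target speller (`build_layout("dataset2_12class")`,
`f = 0.5i + 2j + 6.75` Hz, `phi = (0.5i - 0.5)pi`, 9.25-14.75 Hz). The
decoding task: given a short multichannel EEG window, identify which target
was attended. Wearable devices motivate the hard version of the task — one
to three occipital channels (Oz, O1, O2) rather than a full montage.

## Features: the complex spectrum

Each analysis window is band-pass filtered, transformed per channel by an
FFT, and the real and imaginary parts of the in-band bins are concatenated
as `[Re | Im]` into one feature row per channel. Unlike a magnitude
spectrum, this representation preserves phase, which JFPM deliberately
encodes; a classifier that sees only amplitude cannot separate targets that
share a frequency neighborhood but differ in phase.

Numerical conventions, all configurable:

* **Filter** — 4th-order Butterworth band-pass, 3-45 Hz by default (covers
  every stimulus fundamental of both layouts plus at least two harmonics),
  applied forward-backward (`signal::filtfilt`). Zero-phase filtering is
  deliberate: a causal pass would add frequency-dependent phase distortion
  to exactly the information the features carry. The price is an effective
  2 x 4-pole response, i.e. attenuation is that of the squared magnitude.
* **Spectrum** — un-normalized forward DFT of the zero-padded window at
  `NFFT = round(fs / resolution)` points; default resolution 0.25 Hz and
  band 3-35 Hz inclusive, giving 129 bins and `Nsp = 258` features per
  channel at the defaults. Zero-padding interpolates the spectral grid so
  every stimulus frequency falls near a bin center; `Nsp` is always derived
  from the settings, never hard-coded. The DFT normalization constant is
  irrelevant to the network (batch norm absorbs scale) but is fixed and
  tested against a brute-force DFT oracle.
* **Segmentation** — trials are cut into non-overlapping windows of
  `floor(window_s * fs)` samples; a leftover tail is discarded.

## The networks

`build_ccnn()` is the plain complex-spectrum CNN baseline: a channel-
combining convolution (kernel spanning the channel axis, 'valid' padding,
32 filters), a spectral convolution (kernel `[1 x 20]`, 'same' padding,
32 filters), each followed by batch norm, ReLU and dropout, then one dense
softmax classifier.

`build_atten_ccnn()` extends it in three ways: each convolution becomes a
convolution-attention block; a 144-unit ReLU dense layer is inserted before
the classifier; and each block reweights its 32 feature maps with a
squeeze-and-excitation (SE) module. Inside a block the order is
convolution, ReLU, batch norm, dropout — activation *before* batch norm,
kept exactly as the architecture prescribes even though the reverse is more
common. The SE module computes one scalar weight per filter: a global
average over the spatial axis (squeeze), a bottleneck dense pair
(32 -> 32/`se_ratio` with ReLU, back to 32 with sigmoid; default ratio 4),
and multiplicative reweighting.

The attention wiring is the architecture's distinctive detail (the
*adjusted connection*): the SE weights are computed from the
**dropout-passed** maps, but applied to the maps that **skipped dropout**.
Dropout therefore regularizes only the attention computation, never the
signal path, and at inference — where dropout is the identity — the two
paths coincide, which the test suite asserts bit-for-bit. The
attention-enhanced tensor is the block output; no second dropout is applied
to it.

Two printed details required interpretation, both flagged rather than
silently resolved:

* The first convolution's kernel is printed as `[32 x 1]`, which cannot
  span a 3-channel input axis. It is implemented as 32 filters of kernel
  `[Nch x 1]` — consistent with 'valid' padding collapsing the channel axis
  and with the model's stated role of weighting channels.
* Whether dropout follows the 144-unit dense layer is unstated; none is
  applied (dropout lives only inside the blocks).

Other unstated choices: the SE reduction ratio defaults to 4 (32 -> 8 ->
32, keeping the excitation pair small next to the convolutions); the loss
is categorical cross-entropy (the standard companion of a softmax output);
weights use variance-scaling Gaussian initialization from the seeded RNG;
L2 weight decay (coefficient 0.001, penalty `l2 * sum(w^2)`) applies to
convolutional and dense weight matrices only, not biases or batch-norm
parameters.

## Training and evaluation protocols

Training is mini-batch SGD at learning rate 0.001 for 120 epochs, batch
size 256 for the subject-independent protocol and 16 for the
subject-dependent one. Momentum is unstated in the recipe; the default here
is 0.9, because plain SGD at this learning rate converges very slowly —
`momentum = 0` is one flag away and logged in the configuration.

* `loso_cv()` — leave-one-subject-out: n subjects give n folds;
  segmentation happens before splitting but all segments of a subject stay
  on one side, asserted on every fold.
* `kfold_cv()` — subject-dependent 10-fold: one subject's segments are
  partitioned randomly (seeded) into 10 sets. Note the partition is at
  segment level, as the protocol specifies, so segments of one trial can
  appear on both sides of a fold; subject-dependent accuracies are
  correspondingly optimistic relative to a trial-level split.

Performance is reported as accuracy and information transfer rate,

\[ \mathrm{ITR} = 60\,\frac{\log_2 K + P\log_2 P +
   (1-P)\log_2\frac{1-P}{K-1}}{T} \quad \text{bits/min}, \]

with `T = window + 0.55 s` gaze shift. Below-chance accuracies (`P < 1/K`),
where the formula turns negative, are clipped to chance (ITR 0) with a
message — the community convention. Whether a published ITR is the ITR of
the mean accuracy or the mean of per-fold ITRs is often ambiguous, and the
two differ because ITR is convex in P; `eval_report` objects therefore
carry both aggregations. Model pairs are compared with a two-sided paired
t-test per fold vector (`paired_compare()`), banded ns / * / ** / *** at
0.05 / 0.01 / 0.001, with no multiple-testing correction across window
lengths (matching how such results are conventionally reported; noted in
the report metadata).

## The synthetic generator

Real SSVEP recordings cannot ship with a package; the generator provides
data with the statistical structure the decoder relies on, so the whole
pipeline is testable end to end. A trial for target (f, phi) is

\[ x_c(t) = s_c \sum_h A_h \sin\!\big(2\pi h f (t+\tau) + h\,\varphi\big)
   + \text{noise}, \]

* **Harmonics** — 3 by default with amplitudes (1.0, 0.5, 0.25) uV, the
  typical SSVEP roll-off; harmonics at or above Nyquist are dropped with a
  message. Phase scales as `h * phi`, which is what a common time shift of
  the fundamental implies — so shifting `phi` by pi delays the waveform by
  exactly half a period (a tested property).
* **Channels** — channel k is scaled by `1 - 0.1k` in the montage order
  Oz, O1, O2, POz, ..., Oz strongest (Oz is the conventional single-channel
  choice).
* **Subjects** — each subject draws an amplitude gain (uniform 0.8-1.2), an
  SNR from the requested range, and a response latency `tau ~ N(0, 10 ms)`
  applied as a common time shift — the phase-confound between subjects that
  makes subject-independent decoding hard.
* **Noise** — a 4:1 power mixture of 1/f-shaped Gaussian noise (flat below
  1 Hz) and white noise, identical in level across channels, scaled so the
  strongest channel attains the subject's SNR, defined as signal power over
  noise power in the 3-35 Hz band.
* **Blocks** — every (subject, block) contains each target exactly once in
  randomized order, mirroring speller experiment designs.

What the generator does **not** model: eye blinks, EMG artifacts, electrode
impedance drift, alpha-band structure, non-stationarity within a session,
or realistic inter-channel correlation (noise is independent across
channels). Passing recovery tests on this data therefore demonstrates that
the implementation learns and generalizes the encoded structure — not that
it attains any particular accuracy on real EEG. The published accuracies on
real recordings (which depend on a private wearable dataset and a
downloadable public one) are deliberately out of scope; the public 12-class
MAT files can be analyzed with `load_public_12class()` when present
locally.

```{r example}
library(attenccnn)
layout <- build_layout("dataset2_12class")
epochs <- generate_dataset(layout, n_subjects = 6, n_blocks = 10,
                           duration = 1, fs = 256, n_channels = 3,
                           snr_range = 20, seed = 101)
s1 <- subset_epochs(epochs, which(epochs$subject_ids == "S01"))
report <- kfold_cv(s1, build_atten_ccnn, window_s = 1,
                   train_cfg = train_config(epochs = 30, batch_size = 16,
                                            seed = 102))
report
```

## Problem sizes used by the test suite

The shipped tests and the acceptance script scale the published protocol to
sizes a single CPU handles in minutes; these are the package's reference
experiment definitions:

* **Recovery** — 6 subjects x 10 blocks of 12-class data at 20 dB SNR,
  1 s trials and 1 s windows; 10-fold CV on the first subject at 30 epochs
  (the loss plateaus within ~10 epochs at this SNR, so 30 is comfortable).
  The expectation is >= 90% accuracy, with a label-shuffle control within
  3 binomial SDs of chance (1/12).
* **Directional comparison** — 5 independent datasets of 3 subjects x
  6 blocks at 0-10 dB SNR; one LOSO fold per dataset (S01 held out, both
  other subjects in training), both architectures trained for a fixed
  60 epochs at batch 32. Two aspects of this design matter. First, the
  training must run to convergence: with only ~150 training segments, a
  very short schedule measures convergence speed rather than the models —
  and the deeper attention model converges more slowly, which would bias a
  half-trained comparison against it. Sixty fixed epochs (no early
  stopping) is the longest schedule the reference hardware affords and the
  closest to the full 120-epoch recipe; the batch is scaled to the dataset
  size for the same reason. Second, only one fold per dataset is rotated,
  trading fold coverage for seed coverage at fixed compute. The claim
  checked is directional only: mean held-out accuracy of the attention
  model >= the baseline. Effect sizes on synthetic data are not comparable
  to effect sizes on real EEG and are not asserted.
* **Oracles** — the complex spectrum is checked against a brute-force
  O(N^2) DFT (deviation < 1e-8), attention against a hand-rolled
  squeeze-excite loop (< 1e-6), the paired test against the textbook
  formula (< 1e-10), and both architectures' gradients against central
  finite differences.

## Known limitations

* Training runs on one CPU thread via BLAS matrix products; it is fast for
  the few-channel problems the package targets but does not scale to large
  montages or very deep variants.
* Batch-norm running moments update with a fixed momentum of 0.1; very
  short trainings (a few batches) leave them close to their initialization,
  which mildly blurs the train/inference equivalence the SE-path tests rely
  on. The shipped protocols train long enough for this not to matter.
* The MAT reader covers the subset of MAT v5 used by the public 12-class
  distribution (little-endian numeric arrays, plain or zlib-compressed
  elements); cell arrays, structs and v7.3/HDF5 files are out of scope.
* `kfold_cv()` inherits the segment-level partition of the protocol it
  implements; for a leakage-free subject-dependent estimate at trial level,
  segment after splitting instead.
* With converged training, the synthetic task at 0-10 dB SNR sits near
  ceiling for both architectures, so the directional comparison has little
  dynamic range — differences amount to a few held-out segments and their
  sign can move with the dataset seed. The generator's background noise is
  unstructured, which gives filter-wise attention little to exploit; the
  synthetic check therefore demonstrates that the attention mechanics are
  implemented correctly and do no harm, not the effect size reported on
  real recordings.
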