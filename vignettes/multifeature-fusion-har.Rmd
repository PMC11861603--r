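---
title: "Multi-feature fusion of image-reconstructed accelerometer signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-feature fusion of image-reconstructed accelerometer signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human activity recognition (HAR) from a chest-worn tri-axial accelerometer
asks: given a short window of raw acceleration, which of a fixed set of
activities — walking, stair climbing, postural transitions, jump rope, and
several types of falls — produced it? Classifiers built directly on the raw
1-D series are sensitive to sensor noise and depend on hand-crafted
features. `actifuse` implements the alternative this package is built
around: re-express each 10 s segment (2500 samples x 3 axes at 250 Hz) as
**three complementary 64 x 64 RGB images** and classify the image triple
with a three-branch convolutional network whose per-branch feature vectors
are fused by concatenation. The raw signal is segmented and used as-is: no
filtering, resampling or normalisation is applied before encoding.

## The three encodings

**Spectrogram.** The squared magnitude of the short-time Fourier transform,

$$S(m,\omega) = \Big|\sum_n x[n]\,w[n-m]\,e^{-j\omega n}\Big|^2,$$

computed per axis with a Hann window of length $L$ (1, 2, 5 or 10 s) and
hop $H = L/2$. The one-sided power matrices of the x, y and z axes are
horizontally stacked (frequency vertical, time-by-axis horizontal),
converted to decibels, jointly min–max normalised, mapped through a
256-entry colour lookup table, and bilinearly resized to 64 x 64. With the
default 10 s window on a 10 s segment the transform degenerates to a single
frame — a pure frequency profile per axis — which is the configuration that
performs best in the window-size sweep.

**Recurrence plot (RP).** The classical recurrence plot thresholds pairwise
distances through a Heaviside step, $R_{ij} = \Theta(\epsilon - \|x_i -
x_j\|)$. Here the binarisation is deliberately omitted: the distance matrix
$D_{ij} = |v_i - v_j|$ itself (embedding dimension 1) is used, preserving
the full distance structure. One plot per axis fills one colour channel
(x→R, y→G, z→B), each min–max scaled to [0, 255]. For tractability the
2500-sample series is block-averaged to 256 points before the $O(n^2)$
matrix, an approximation of computing the full-resolution plot and resizing
it. Because $|v_i - v_j|$ is unchanged by a global offset, the encoding is
exactly translation-invariant — magnitude patterns are captured, signal
polarity is not, which is why mirrored activities (left vs right fall) look
alike to this channel.

**Multi-channel plot (MP).** All 7500 values of a segment are jointly
min–max scaled to the real interval [0, 255]; each scaled value $v$ is
split into its integer part (R channel), first-to-second decimal digits
(G) and third-to-fourth decimal digits (B) — an Iss2Image-style
value-to-pixel encoding. Each axis's 2500 pixels form a 50 x 50 tile
(row-major); the three tiles are stacked vertically (150 x 50) and resized
to 64 x 64. The decomposition is exactly invertible before resizing:
$|v - (R + G/100 + B/10^4)| < 10^{-4}$. The digit wording admits a second
reading (axes assigned to digit groups); the per-value decomposition was
chosen because it preserves one pixel per sample and the full dynamic range
of every axis.

## The classifier

Each branch maps one 64 x 64 x 3 image through five blocks of (3 x 3
same-padding convolution, ReLU, 2 x 2 max pooling), with channel schedule
32-64-128-128-64, so the spatial chain is 64→32→16→8→4→2 and the final map
is 2 x 2 x 64 (flattened 256). A fully connected layer lifts this to a
1024-dimensional feature vector. The three branch vectors are concatenated
(3072) and passed through dense layers of 256 and `n_classes` units with a
softmax output. Only the endpoints of the schedule (final 64 channels, 1024
features, 256 head units) are fixed by the architecture; interior channels
are configurable. The default schedule yields 2,523,919 trainable
parameters at 15 classes — about 2.5 million, in the same regime as the
published figure for this architecture family. The 1-D baseline mirrors the
topology with length-3 1-D kernels over the raw (2500, 3) segment and
pooling factors (5, 5, 5, 5, 1), giving the same 4 x 64 = 256 flattened
feature and head sizes, with a single input and no fusion.

Training follows a fixed protocol: categorical cross-entropy, Adam at
learning rate 0.005, batch size 8, 50 epochs by default, and a
reduce-on-plateau schedule that multiplies the rate by 0.7 whenever the
validation loss has stagnated for 3 consecutive epochs (so two plateau
events leave the rate at $0.005 \times 0.7^2 = 0.00245$). Pixel inputs are
scaled to [0, 1]; raw-series inputs are standardised by the training
partition's pooled mean and standard deviation. Weight initialisation and
shuffling fan out from one integer seed. The convolution, pooling and Adam
kernels are implemented in C++ (im2col + GEMM in single precision via
Armadillo); runs are bit-reproducible given the seed and a fixed BLAS
thread configuration.

## Evaluation

`compute_metrics()` reports top-1 and top-3 accuracy, macro one-vs-rest
precision and recall, macro one-vs-rest ROC AUC (via pROC), and the
multiclass confusion matrix. Macro averaging was chosen because the
datasets this package targets are class-balanced, in which case multiclass
accuracy and macro recall coincide; a class never predicted contributes
precision 0. Splits are always **subject-independent**: subjects, not
segments, are partitioned (test fraction of all subjects, validation
fraction of the remaining training subjects, default 0.2 and 0.25), so no
person contributes to both training and evaluation. The three harnesses —
`window_size_sweep()`, `method_comparison()`, `noise_sweep()` — repeat
training over consecutive seeds and report mean (sd) per condition;
repeats re-seed training but keep the subject partition fixed (re-splitting
is available by calling `split_by_subject()` with a different seed). In the
noise sweep, Gaussian noise is added to every raw value of the test
segments *before* re-running the image reconstructions, and noise levels
are expressed as percentages of the dataset's pooled standard deviation
(`dataset_sigma()`); the command-line default ladder is
[22.5, 55, 110, 165, 220, 275] raw counts, i.e. roughly 5–50% of a pooled
sigma near 551 (the rounded 5% rung of 22.5 is kept for convention;
explicit values may always be passed).

## The synthetic generator

The datasets this method was developed for are subject-private, so the
package ships a generator whose defaults define the study conditions used
by every test. Each of the 15 classes is an *archetype* of one of four
kinds: periodic (gait: fundamental + two harmonics at a class cadence,
e.g. 1.5 Hz walking ≈ 90 steps/min, *plus cadence-locked step-impact
pulses* — the short broadband transients of heel strikes, without which a
spectrogram of smooth sinusoids carries almost no class information above
the stride band); postural transitions (smooth 1–2 s gravity reorientation
with a movement burst); transient falls (quiescence, an impact spike of
3.5–5.5 g at a random time in the middle third of the window, then
reoriented gravity); and static postures. Confusability is built in
deliberately: fall-forward and fall-on-knees differ only in impact
magnitude and post-fall pitch, and left/right falls are mirror images
across the lateral axis. Per-subject log-normal amplitude and frequency
multipliers (sd 0.15) are drawn once per subject, inducing the
intra-subject correlation that motivates subject-level splitting. The
raw-count scale (989 counts per g) was calibrated once so that the pooled
standard deviation of the full 15-class default dataset is near 551 raw
counts, making the noise ladder meaningful; it is not revisited.

What the generator does *not* emulate: biomechanically realistic limb
dynamics, sensor drift/saturation, heteroscedastic or coloured noise, and
activity mislabelling. Passing tests therefore demonstrate that the
pipeline is correct and that the method's *directional* claims (fusion is
not dominated by any single encoding; fusion degrades less than the raw
1-D baseline under added noise) hold under controlled conditions — they do
not certify accuracy on real recordings.

## Numerical choices

* Decibel floor: powers are clipped at $10^{-12}$ before `10*log10`, so an
  all-zero signal maps to a uniform image rather than $-\infty$.
* Degenerate min–max (max = min): defined as all zeros for RP channels and
  MP pixels — a constant signal carries no contrast.
* MP digits use truncation (floor) at the fourth decimal with a $10^{-6}$
  guard, keeping decimal values such as 123.4567 (not exactly representable
  in binary) on the intended grid cell.
* Resizing is bilinear (EBImage), applied before 8-bit quantisation.
* Argmax ties break toward the lowest class index; top-3 uses the stable
  ordering of probabilities.
* The colormap is the 256-entry viridis table; `colormap = "gray"`
  replicates intensities across channels for ablations.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run two study sizes, chosen as
the package's scaled-down standard conditions: an end-to-end study of 4
classes (WK, JR, SC, FF) x 40 subjects x 5 repetitions trained for 10
epochs, and a comparison study of 4 classes x 16 subjects x 3 repetitions
trained for 4 epochs over 4 (tests) or 2 (acceptance script) consecutive
seeds. Full-scale runs (15 classes, 210 subjects, 50 epochs) use exactly
the same code paths via `synthetic_config()` and `train_config()`.

## Known limitations

* At the default 10 s window the spectrogram has a single frame; together
  with the 64-pixel frequency axis this compresses the gait band into few
  rows, and the spectrogram-only model converges noticeably more slowly
  than the RP/MP models at the default learning rate.
* The RP block-averaging to 256 points is an approximation; pathological
  signals with structure entirely above the decimated bandwidth would be
  smoothed out.
* Single-precision GEMM bounds reproducibility across BLAS builds; results
  are bit-stable only on a fixed build with fixed threading.
* The 1-D baseline shares the channel schedule but not the receptive-field
  scale of the 2-D branches; it is a topology mirror, not a tuned
  competitor.
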