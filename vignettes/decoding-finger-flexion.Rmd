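---
title: "Decoding continuous finger flexion from ECoG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding continuous finger flexion from ECoG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogflex)
```

## The problem

Electrocorticography (ECoG) records cortical potentials directly from the
brain surface at kilohertz rates. During voluntary finger movement, the
amplitude of high-gamma activity (roughly 70--170 Hz) over motor cortex rises
and falls with the movement, which makes continuous trajectory decoding
possible: given a multichannel ECoG recording and a dataglove trace of the
five fingers' flexion, learn a map from the neural signal to the five
continuous trajectories. The standard benchmark pairs 1 kHz ECoG (tens of
channels, electrode order scrambled by the provider, so no spatial layout is
available) with 25 Hz glove traces under a cued paradigm: a 2 s cue names a
finger, the subject flexes it several times, then rests 2 s.

`ecogflex` implements one complete decoding pipeline: signal conditioning,
a 3D wavelet amplitude representation, overlapping sliding-window
segmentation, a 1-D dilated-convolution encoder / transposed-convolution
decoder, and Pearson-correlation evaluation — plus a synthetic generator so
the whole chain can be validated without any external download.

## Signal path

1. **Normalization.** Each channel is z-scored (mean removed, divided by the
   standard deviation) and then the median of the standardized trace is
   subtracted, leaving every channel with median exactly zero. The median
   step follows the z-score; the two orderings differ only for skewed
   channels, and we follow the order in which the steps are naturally
   described (standardize, then remove the median).
2. **Filtering.** A 4th-order Butterworth band-pass keeps 40--300 Hz, the
   band that carries movement information while excluding slow physiological
   drift and high-frequency artifacts. A comb of biquad notches (quality
   factor 30) removes 60 Hz mains interference and its harmonics (120, 180,
   240, 300 Hz at a 1 kHz rate). Both filters run forward--backward
   (zero-phase), because any group delay would shift the neural signal
   relative to the glove trace and corrupt the regression targets. The
   filter order and notch Q are our choices; the contracts the tests enforce
   are pass-band loss below 3 dB and stop-band attenuation above 20 dB.
3. **Wavelet spectrogram.** Each channel is convolved with complex Morlet
   wavelets `psi_f(t) = A exp(-t^2 / (2 sigma^2)) exp(2*pi*i*f*t)` with
   `sigma = n_cycles / (2*pi*f)`, on a log-spaced grid of center frequencies
   spanning 40--300 Hz. The amplitude `|W|` forms a 3D array
   (channel x frequency x time). Defaults: 40 frequencies and
   `n_cycles = 7`. Both counts are free parameters of the analysis; 40
   frequencies resolves the log band at roughly 5% spacing and 7 cycles is
   the conventional compromise between time and frequency resolution for
   high-gamma work. `A` normalizes each sampled wavelet to unit L2 norm so
   that amplitudes are comparable across frequencies. Amplitude rather than
   power is the default output (a `power` switch squares it): amplitude has
   the smaller dynamic range, which keeps the downstream normalization-free
   network better conditioned.
4. **Downsampling and alignment.** The spectrogram's time axis is reduced
   from 1 kHz to 100 Hz by block-averaging consecutive 10-sample blocks
   (an anti-aliased envelope estimate, rather than naive decimation), and
   the glove traces are raised from 25 to 100 Hz by a cubic spline that
   passes through every original sample. Both streams are truncated to the
   shorter common length, so they align frame for frame.

## Windowing

A window of `l = 256` frames (2.56 s at 100 Hz) slides with stride `s`
(default 1) over the `T` aligned frames, producing
`N = floor((T - l) / s) + 1` samples. Each sample flattens the
(channel, frequency) axes channel-major into a single feature axis of size
`c * f`, paired with the aligned `5 x l` target slice. `l` must be divisible
by 32 because the encoder halves the time axis five times. Windows are
materialized lazily from the flattened feature matrix: a dense stride-1
segmentation of a long recording would not fit in memory as an explicit
array, and a batch of indices is all the optimizer ever needs.

At test time, predictions from non-overlapping tiled windows (`s = l`) are
concatenated by default; an overlap-averaging mode reconstructs each frame
as the mean of every window prediction covering it.

## The network

- **Feature reduction:** a kernel-3 1-D convolution maps the `c * f` input
  features to 64 channels. (The reduction kernel is "3 x 3" in the
  two-axis picture of (feature, time); operating on the flattened 1-D
  sequence this is kernel size 3.)
- **Encoder, 5 stages:** each stage applies a dilated 1-D convolution
  (kernels 7, 7, 5, 5, 5; dilations 1, 2, 3, 1, 2 — a sawtooth pattern that
  grows the receptive field without parameter cost), layer normalization
  over the channel axis, GELU, dropout 0.1, then max-pool(2). The pooled
  output is saved as the stage's skip tensor. Widths run
  64, 128, 256, 512, 512.
- **Decoder, 5 stages:** each stage concatenates the matching encoder skip
  (exactly doubling the feature axis, since decoder widths mirror the
  encoder in reverse), applies a standard conv block (mirrored kernels
  5, 5, 5, 7, 7 — the reference recipe leaves decoder kernels unstated, so
  we reuse the mirrored encoder kernels), then upsamples x2 with a
  learnable transposed convolution (kernel 2, stride 2, the exact inverse
  of pool(2); no cropping needed). An ablation switch replaces it with
  fixed linear interpolation.
- **Head:** a 1x1 convolution maps the final 64 channels to the 5 finger
  outputs at every time step. The network is length-preserving end to end;
  the bottleneck sits at `l / 32`.

All padding is "same"-style (dilated convs padded by `d * (k - 1) / 2`), so
only pooling changes the time length. Weights start from fan-in-scaled
uniform draws under a recorded seed. Forward and backward passes are written
out explicitly (with Rcpp/Armadillo kernels for the convolutions, pooling
and upsampling); a numerical-differentiation test pins the analytic
gradients to ~1e-7 relative error.

With the default widths the parameter count is dominated by the wide
encoder/decoder stages and the reduction layer over `c * f` inputs; the
per-layer ledger is available via `parameter_ledger()` and is reported
rather than asserted, since published parameter totals for this family of
models are sensitive to details (channel counts per subject, factorized
convolutions) that the recipe does not pin down.

## Training and evaluation

Adam with learning rate 8.42e-5 and L2 weight decay 1e-6 minimizes

```
loss = MSE(pred, target) + lambda * (1 - mean cosine similarity)
```

with the cosine term computed per (sample, finger) along the window's time
axis. The mixing weight `lambda` is unstated in the reference recipe;
`lambda = 1` (equal weighting) is the neutral default, configurable and
logged. Batch size (64), epoch cap (40), early stopping on validation mean
Pearson r (patience 5) and the chronological 90/10 train/validation split
are likewise desk-scale defaults; the split is chronological, never
shuffled, to avoid temporal leakage between overlapping windows. Training
is fully seeded (initialization, data order, dropout) and single-threaded
BLAS reproduces loss curves bit-for-bit.

Evaluation computes the Pearson correlation between each decoded and true
finger trajectory over the stitched test span, and their mean. Zero-variance
truth (a finger that never moves in the span) has no defined correlation
and is excluded from the mean with a warning rather than silently scored 0.

## The synthetic generator

`synth_config()` describes a recording that emulates the cued paradigm: 2 s
cue / 2 s rest blocks cycling through the five fingers, each cue containing
3--5 raised-cosine flexion bumps; trajectories live in [0, 1] and are
sampled at 25 Hz. Each finger owns a disjoint carrier band inside 70--170 Hz
(the high-gamma range) and two of the sixteen channels; an assigned
channel carries band-limited carrier noise whose amplitude is proportional
to the finger's trajectory, so band amplitude envelopes encode the targets
exactly as movement-locked high-gamma does. On top of that every channel
receives pink (1/f) noise, a 60 Hz line component strong enough to dominate
neighboring spectral bins by over 20 dB (so the notch stage is doing real
work), and a small shared Gaussian term. A 120 s recording is split
chronologically 2:1 into train/test files in the competition's MATLAB
layout.

What the fixture does *not* emulate: cortical biophysics, cross-channel
mixing, electrode-specific noise floors, non-stationarity, or fingers
encoded jointly rather than in disjoint bands. Passing the end-to-end tests
therefore demonstrates that the pipeline's statistical machinery recovers a
planted band-power code; it does not certify performance on real cortical
data, where the code is weaker and shared across channels.

## Problem sizes and numerical choices

The shipped tests run the full chain at deliberate desk scale: the 120 s
default fixture (16 channels, 40 wavelet frequencies, 8,000 training
frames), a width-reduced network with stage widths capped at 128, minibatch
16, and roughly 200--360 optimization steps per run. At that scale the
planted signal is recovered with mean test correlation around 0.8--0.9
across seeds, the full model outperforms the all-disabled variant
(dilations off, linear upsampling) near convergence, and transposed
convolution outperforms linear upsampling. Early in training those
orderings can invert — simpler upsampling learns faster before the
learnable path overtakes it — which mirrors why ablation comparisons are
made near convergence, not at fixed small step counts.

Other numerical choices: layer-norm epsilon 1e-5; GELU uses the exact
normal CDF; max-pool ties break toward the earlier frame; cosine terms with
a zero-norm vector contribute similarity 0 with zero gradient (keeping the
loss finite when a window's target is all-rest); Morlet kernels are
truncated at 5 sigma and applied by FFT convolution; the spectrogram's
trailing frames that do not fill a 10-sample block are dropped.

## Known limitations

- The alternative-wavelet spectrograms (Haar / Daubechies-4 / Symlet-4,
  for the wavelet-family ablation) use cascade-constructed real mother
  wavelets sampled at each scale; real wavelets yield oscillatory
  coefficients rather than smooth analytic envelopes, which is precisely
  why they underperform Morlet — but the construction for compactly
  supported wavelets on a continuous frequency grid is a convention, not a
  standard.
- The MAT-file reader covers real numeric arrays (plain or
  zlib-compressed), which is all the competition release and the fixtures
  use; it is not a general MATLAB parser.
- Training on a full competition recording at dense stride with the default
  widths is CPU-feasible but slow; the package is tuned for correctness and
  desk-scale experimentation, not GPU-class throughput.
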