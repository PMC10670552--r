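---
title: "Methods: ECG signal quality assessment with ecgsqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG signal quality assessment with ecgsqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsqa)
```

## The problem and the model

Surface ECG recordings pick up four canonical families of contamination:
baseline wander (slow drift, typically respiration-driven, below ~0.5 Hz),
powerline interference (a 50 or 60 Hz tone), muscle/EMG noise (broadband,
roughly 20–120 Hz) and electrode motion artifacts (abrupt baseline steps
and decaying spikes). `ecgsqa` classifies a fixed-length single-lead
segment as *acceptable* or *unacceptable* for diagnostic use.

The pipeline is: min-max amplitude normalization to [−1, 1] per segment,
a Hann-windowed short-time Fourier transform (STFT) magnitude spectrogram,
and a CNN-LSTM binary classifier. The time-frequency representation is a
natural fit: the contamination families live in distinct, partly
non-stationary spectral bands, the convolutional blocks extract local
spectral patterns per time frame, and the LSTM aggregates their evolution
across the segment. The key assumptions are that (i) a 10-s window is long
enough to judge quality and short enough to carry a single label, (ii)
quality is expressible from amplitude-normalized data, so absolute
calibration (mV vs arbitrary units) is irrelevant, and (iii) the two
classes are separable from spectral texture alone, without beat
delineation.

## Spectrogram geometry

The STFT splits the signal into frames of `frame_length` samples advancing
by `frame_step`; each frame is tapered by the *periodic* Hann window
`w[n] = 0.5 − 0.5·cos(2πn/N)` (denominator `N`, so `w[0] = 0` and, for
even `N`, the center weight is exactly 1) and Fourier-transformed; the
one-sided magnitude (`frame_length/2 + 1` bins) is kept. There is no
padding: the tail that does not fill a frame is dropped, so an input of
length `L` yields `T = floor((L − frame_length)/frame_step) + 1` frames.

The defaults `frame_length = 256`, `frame_step = 128` are the conventional
power-of-two, 50%-overlap pair for which a 10-s, 500-Hz segment (5000
samples) produces the classifier's fixed input of 38 × 129 — at 500 Hz
this is a 512-ms analysis window with 1.95-Hz bin spacing, a sensible
time–frequency trade-off for ECG content. Magnitude (not power, not
log-magnitude) values are passed on; the classifier's own normalization
layer standardizes each frequency bin on the training corpus, which makes
a log transform redundant for class separation in practice.

## The classifier

Topology (all sizes configurable through `model_config()`):

| stage | default | notes |
|---|---|---|
| input | (38, 129) | frames × bins |
| normalization | per-bin mean/sd | adapted on the training set, frozen thereafter |
| conv block 1 | 64 filters, kernel 3 | 1-D over time, "same" padding, ReLU, max-pool 2, dropout 0.3 |
| conv block 2 | 128 filters, kernel 3 | same structure |
| dense (time-distributed) | 64 units, ReLU | per remaining frame |
| LSTM | 64 units | final hidden state summarizes the sequence |
| dense head | 32 units, ReLU | after dropout 0.3 |
| output | 2-unit softmax | config switch: 1-unit sigmoid |

Time frames are the sequence dimension the LSTM consumes; frequency bins
are the per-step features. Two max-pools of width 2 reduce 38 frames to 9
LSTM steps. The default loss is sparse categorical cross-entropy over a
2-unit softmax; because a sigmoid output is the other convention commonly
paired with binary quality labels, a 1-unit sigmoid with binary
cross-entropy is available (`output_units = 1`,
`loss = "binary_cross_entropy"`) rather than silently merged — the two
parameterizations are not interchangeable and the choice is explicit
configuration. Labels are encoded unacceptable = 0, acceptable = 1.

Training uses Adam (learning rate 1e-4 — deliberately below the usual
1e-3, which converges too aggressively on these small, highly separable
spectrogram corpora), batch size 32, up to 50 epochs with early stopping
on validation loss (patience 10, best weights restored). Weights are
Glorot-uniform initialized with the LSTM forget-gate bias set to 1. The
whole network, forward and backward, is implemented in-package as BLAS
matrix operations (batches are held time-major so convolutions become one
matrix product over unfolded frames); the analytic gradients of every
layer are verified against central finite differences in the test suite,
which is the correctness anchor for the engine.

Determinism: given a fixed seed, initialization, shuffling and dropout
masks are reproducible, and training is bit-identical under a fixed thread
configuration. With a multi-threaded BLAS, floating-point reductions may
reorder; same-session reruns remain identical, but cross-machine
bit-identity is best-effort.

## Corpus construction and splitting

`build_ratio_corpus()` assembles a corpus at a requested
acceptable:unacceptable ratio by keeping *all* of the limiting class and
uniformly subsampling the other — never duplicating records, which would
fabricate data. It returns the largest n with `round(n·r)` acceptable
items available on both sides; the achieved fraction is within one sample
of the target.

`split_corpus()` apportions records to train/validation/test by the
largest-remainder method, so partition sizes are exact to within one item.
By default the split is fully random; `group_aware = TRUE` constrains all
records sharing a `group_id` (e.g. the 12 leads of one recording) to a
single partition, closing the leakage channel by which correlated leads
can inflate test scores. Group-aware mode places whole groups greedily by
relative deficit, so sizes are then exact only to group granularity; a
single group larger than the training target is an error rather than a
silent distortion.

## The synthetic generator

`make_clean_ecg()` produces the standard sum-of-Gaussians PQRST phantom:
five Gaussian bumps per beat at fixed offsets relative to the R wave
(P −200 ms, Q −35 ms, R 0, S +35 ms, T +280 ms; amplitudes 0.14, −0.12,
1.0, −0.25, 0.32; widths 28, 10, 13, 12, 60 ms), with beat-to-beat RR
jitter uniform within ±4% of the nominal period. This is adequate for a
*quality* classifier — it provides realistic spectral structure
(dominant QRS energy, harmonics of the heart rate) — and is not intended
as physiology: no arrhythmia, no respiratory modulation, no multi-lead
geometry.

`add_noise()` realizes one of the four contamination families (or a random
composite) and scales it analytically so the realized
`10·log10(P_signal/P_noise)` equals the requested SNR exactly. Defaults in
`make_labeled_corpus()`: acceptable records are clean or contaminated at
SNR uniform in [10, 20] dB, unacceptable at [−10, 0] dB, leaving the
0–10 dB band unused as a deliberate margin between classes. The
experiment harness (`run_config()`) trains at a 20-dB class gap
(acceptable ≥ 10 dB, unacceptable ≤ −10 dB): classes that are separable by
construction, so end-to-end tests probe the machinery rather than the
frontier of the task.

Consequently, passing tests demonstrate that the pipeline — generation,
segmentation, spectrogram, training, evaluation — is correct and
reproducible, *not* that the classifier reaches any particular accuracy on
clinical recordings, whose noise is more diverse and whose label boundary
is far softer than an SNR threshold.

## Numerical and interface decisions

- **Resampling** is Fourier-domain band-limited interpolation (spectrum
  truncation or zero-padding, Nyquist bin kept real): anti-aliased by
  construction and phase-neutral, so a down–up–down round trip returns the
  band-limited content with no group delay to compensate. Output length is
  `round(L · target_fs / fs)`.
- **Normalization degenerate case**: a constant segment maps to all zeros
  (the midpoint), not NaN.
- **Segmentation discard rule**: a labeled region yields
  `floor(duration / window_s)` non-overlapping windows anchored at the
  region start; regions shorter than one window, and tail remainders, are
  discarded.
- **Decision tie-break**: a segment with acceptable-probability exactly at
  the threshold is labeled unacceptable — the conservative direction for a
  quality gate. Multi-window leads in `predict_file()` take the majority
  label, ties again unacceptable.
- **Positive class**: acceptable, for all of Se/Sp/F1; configurable
  (`positive = "unacceptable"`) since reporting conventions differ.
  Metrics with zero denominators are returned as `NA` and flagged, never
  as 0.
- **Model store**: a single JSON file with a mandatory version field,
  the full configuration, normalization statistics, weights at 17
  significant digits (lossless for IEEE doubles), and the training
  history; reloaded models predict bit-identically.
- **WAV input**: a minimal RIFF codec (PCM 16/32-bit and IEEE float)
  reads and writes the files directly; integer PCM is scaled to [−1, 1).
  Amplitude units are irrelevant after per-segment normalization, so no
  calibration is attempted.

## Problem sizes used by the test suite

Unit and property tests run on corpora of 10–120 segments with a reduced
network (8/16 filters, 16 LSTM units). The end-to-end check trains the
full-size default network on 1800 segments (with 200 for validation) at
the 20-dB class gap and evaluates 400 held-out segments, requiring F1 of
at least 95%; the class-ratio harness (85:15 vs 50:50 training, shared
balanced test set) is exercised at 120 training segments per ratio. These
sizes were chosen as the smallest at which the respective claims are
meaningfully tested.

## Known limitations

- The synthetic noise families are stylized; real electrode motion and
  mixed clinical artifacts are harder, and no synthetic corpus calibrates
  to a clinical label boundary.
- Single-channel, fixed-length input only: leads are classified
  independently, and records are conformed to the model's rate and window
  by resampling and windowing — there is no variable-length or streaming
  mode.
- The engine is CPU-oriented; training scales linearly in corpus size and
  epochs and is intended for corpora of order 10⁴ segments, not 10⁶.
- Three-level or finer quality annotations must be mapped to the binary
  labels by the caller; no canonical mapping is imposed.
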