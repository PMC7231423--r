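---
title: "Methods: EEG windowing, time-frequency fusion and transfer classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG windowing, time-frequency fusion and transfer classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectroseize)
```

## The detection problem

Seizure detection is cast as binary classification of fixed-length EEG
windows. The cross-subject (patient-independent) protocol pools windows
from all subjects before shuffling and splitting, so one classifier serves
every patient. `spectroseize` implements that protocol end to end and is
deliberately testable offline: a synthetic-EEG generator with labeled
seizure intervals stands in for clinical recordings at every stage.

## Windowing

**Step one (sliding).** A window of `lengthS = 180` s moves from time 0
with `overlapFrac = 0.30`, i.e. stride `180 × 0.7 = 126` s. A window is
labeled positive iff it overlaps any annotated seizure interval by a
strictly positive duration. Windows are half-open `[start, start+180)`
and overlap is computed on the half-open intersection — a window whose
edge merely touches a seizure boundary is negative. The half-open
convention removes the double-counting ambiguity that an inclusive
definition would create at shared endpoints.

**Step two (positive augmentation).** Seizures are rare, so positive
windows are oversampled: for each interval `[t1, t2]` windows start at
`t1, t1+1, t1+2, …` seconds and are kept while they overlap the interval
by at least `minOverlapS = 3` s. For integer-second annotations on a long
record this yields `floor(t2 − t1) − 2` windows; a 3 s seizure yields
exactly one and a 2 s seizure none. Windows that would run past the
record end are dropped, never truncated, because every image must span
exactly one full window. Near-duplicate windows 1 s apart are all kept —
oversampling the seizure epoch is the point of the step.

Note the two steps use different thresholds (any positive overlap vs.
≥ 3 s); both are exposed as parameters, and the defaults keep the two
rules as stated independently rather than harmonizing them, since the
choice measurably changes the label of boundary windows.

## Time-frequency images

Each window's three bipolar channels (FP2-F8, F8-T8, T8-P8 — temporal
derivations in which ictal rhythms are comparatively prominent) are
transformed with the short-time Fourier transform: frames of
`winSamples = 413` samples, tapered and Fourier-transformed, one-sided
magnitude. At 256 Hz a 180 s window has 46080 samples, giving
`floor(413/2)+1 = 207` frequency bins.

**Frame advance.** The package's documented hop is `hopSamples = 204`
(overlap 209 samples ≈ 50.6 %), the largest hop that produces exactly
`floor((46080 − 413)/204) + 1 = 224` full frames with no padding — chosen
so the spectrogram geometry is exactly 207 × 224 under the default
segment length. A literal 50 % overlap (hop 206 or 207) would give
221–222 frames. The hop is configurable.

**Taper.** A periodic Hann window is the default (the standard
spectrogram taper; it controls leakage at modest resolution cost);
Hamming and rectangular tapers are available, the latter mainly for
analytic tests where bin positions have closed forms.

**Scaling and fusion.** Per channel: `log10(mag + eps)` with
`eps = 1e-12` (CNN inputs need bounded dynamic range; the floor keeps
zero-magnitude bins finite), then min-max normalization to [0, 1] per
image channel, then bilinear resize of the frequency axis 207 → 224.
The three planes are stacked red/green/blue in the fixed electrode order.
Rows are oriented low frequency at the bottom; tests address frequency
content through the bin→row mapping (`imageRowsForBand()`) rather than
the orientation. Without log scaling, min-max normalization is invariant
to linear signal gain, which the test suite asserts.

## Dataset and splits

Images from all records are pooled (`buildDataset()`); records missing a
required channel are skipped with a warning rather than failing the
batch. The split (`splitDataset()`) is a seeded uniform permutation cut
at 60/20/20: train `round(0.6N)`, validation `round(0.2N)`, test the
remainder (R's `round()`, i.e. half-to-even at exact .5 boundaries).

The pooled protocol is **not subject-stratified**: windows from one
subject — including overlapping windows 1 s apart from the same seizure —
can land in both train and test. That is the protocol being modeled, and
it is optimistic for generalization claims; `leaveSubjectOutSplit()` is
provided as a stricter, off-by-default alternative.

## Classifiers

All models share one shape: a frozen convolutional backbone, global
average pooling or flattening, two trainable fully connected layers, and
a 2-neuron softmax trained with softmax cross-entropy (natural log;
predicted probabilities clipped to `[1e-12, 1]`).

* **VGG16 / VGG19** specs use flattening (7×7×512 → 25088 features) and
  conventionally FC sizes 4096 × 4096; **ResNet50** uses global average
  pooling (2048 features) and 2048 × 2048. These backbones require
  pretrained ImageNet weights, which the package does not bundle;
  building them raises an informative error. Their specs remain useful
  for exact trainable-parameter accounting
  (`nTrainableParams()` = d·f₁ + f₁ + f₁·f₂ + f₂ + 2f₂ + 2).
* **tiny_random** is a first-class offline backbone: three 3×3
  convolution blocks (8, 16, 16 filters; ReLU; max pooling 4, 4, 2)
  mapping 224×224×3 to 7×7×16. Its weights are Glorot-uniform under the
  build seed and permanently frozen, making it a fixed random nonlinear
  embedding — the same role a pretrained extractor plays, minus the
  learned filters. Random convolutional features are a known-adequate
  basis when classes are strongly spectrally separated, which is exactly
  the synthetic regime.

**Feature normalization.** A pretrained backbone arrives with scale
conventions baked in; a random one does not, and its pooled features have
tiny, uneven variances that stall first-order optimizers. `trainModel()`
therefore estimates per-feature mean and standard deviation on the
training partition once, freezes them into the model, and applies them at
every subsequent forward pass (training and inference alike) — the
frozen-statistics analogue of a normalization layer. Zero-variance
features get unit scale.

**Optimization.** Two recipes are built in. The default (`trainConfig()`)
is SGD with learning rate 0.001 and per-update decay `1e-5` interpreted
multiplicatively (`lr_t = lr/(1 + d·t)`, the classic Keras semantics),
batch 64. `resnetTrainConfig()` is Adam (β₁ = 0.9, β₂ = 0.999, lr 0.001,
batch 16) with a reduce-on-plateau schedule: learning rate × 0.8 after 5
epochs without validation-loss improvement. Both cap at 500 epochs and
stop once validation loss has not descended for 20 consecutive epochs;
the head weights at the best validation loss are restored afterwards
(standard practice; the training loop's epoch log records loss, accuracy
and the current learning rate). Weight initialization is Glorot-uniform
and batch order is shuffled under the run seed, so runs are exactly
reproducible.

## Metrics

`computeMetrics()` implements accuracy, precision, recall and the
Matthews correlation coefficient from TP/TN/FP/FN. Any zero denominator
yields the defined value 0 with a diagnostic message rather than NaN, so
sweeps never abort on a degenerate confusion matrix. Multi-run summaries
(`evaluateRepeated()`) average per-run metrics arithmetically — the mean
of metrics, not metrics of pooled counts.

`confusionFromRates()` inverts the formulas: given printed accuracy,
recall and precision plus a test size and prevalence, it reconstructs
real-valued counts (erroring if any count comes out negative, i.e. the
rates are inconsistent) and reports the conservation residual. Feeding
the counts back through `computeMetrics()` checks whether a published
mcor is consistent with its published companion rates — at four printed
decimals the reconstruction is accurate to about ±0.002.

## The synthetic generator

`generateRecord()` emulates what the pipeline actually consumes:

* 256 Hz sampling, three channels;
* background = 1/f^β broadband noise (β = 1, SD 10 µV, generated by
  spectrum-shaping white noise, hence exactly zero-mean) plus a 10 Hz
  alpha rhythm at 20 µV — amplitudes in the range of adult scalp EEG;
* seizures = an added 5 Hz sinusoid (inside the ictal 3–7 Hz band) at
  gain 5 × the background rhythm, with half-second raised-cosine ramps,
  shared timing and independent phases/noise across channels.

The ramped sinusoid is deliberately *not* a spike-wave complex: the
pipeline requires only a time-localized spectral signature, and the
simple form keeps band-power oracles closed-form (the in-band gain
implies an inside/outside band-power ratio well above 4, which tests
check with an independent periodogram). The generator does not model
artifacts, eye blinks, electrode pops, inter-channel correlation or
nonstationary background — so a passing test suite demonstrates correct
plumbing and learnability of separable spectral classes, not clinical
performance on real EEG.

## Numerical conventions and problem sizes

* Half-open interval arithmetic everywhere; 1e-9 slack absorbs float
  noise at window-count boundaries.
* EDF samples quantize to 16 bits over each channel's physical range;
  round-trip error is bounded by one quantization step. Annotation times
  are written as integer seconds (the CHB-MIT convention) but held as
  float seconds internally.
* Split indices are 1-based.
* The test suite exercises the full path at desk scale: property loops
  use hundreds to a thousand random geometries, and the end-to-end check
  trains the tiny backbone on ~400 balanced synthetic images for ≤ 30
  epochs, reaching ≥ 0.95 held-out accuracy in a few minutes on one CPU
  — sizes chosen to make the complete suite routinely runnable on a
  laptop.

## Known limitations

* No EDF+ event annotations; channel variants are resolved only as far
  as bipolar-from-referential subtraction.
* The pretrained backbones cannot be instantiated without their weight
  files; published headline accuracies on clinical data are therefore
  out of reach by design, and the package's claims are confined to what
  its own tests compute.
* The pooled split's optimism (above) is inherent to the protocol, not a
  bug; use `leaveSubjectOutSplit()` when generalization across patients
  is the question.
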