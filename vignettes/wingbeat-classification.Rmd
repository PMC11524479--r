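---
title: "Noise-robust wingbeat classification: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-robust wingbeat classification: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeatr)
```

## The problem and the signal model

A flying mosquito produces a quasi-harmonic flight tone: a fundamental
frequency equal to its wingbeat rate (roughly 350–750 Hz depending on
species and sex; around 512 Hz for female *Aedes aegypti*) plus a few
harmonics. Species differ in their typical fundamentals, but the ranges
overlap, and in the field the tone is buried under trap-fan hum,
vehicles, animals and human activity. `wingbeatr` trains a classifier
on raw 300-ms waveform epochs and makes it robust to such noise by
simulating noisy recordings during training.

A noisy epoch is modeled as pure addition,

$$\mathbf{x}_{nw} = G \cdot \mathbf{x}_w + \mathbf{x}_n,$$

where $\mathbf{x}_w$ is a clean wingbeat epoch, $\mathbf{x}_n$ a random
equal-length segment of an environmental-noise pool, and the gain
factor $G > 0$ sets the wingbeat's amplitude relative to the noise —
physically, how close the mosquito flies to the microphone. `overlay()`
implements exactly this sum and deliberately does **not** clip the
result to $[-1, 1]$: clipping would distort the training distribution.
Only on export to 16-bit WAV (`export_eval_set()`, `write_wav()`) is
clipping applied, because the format requires it.

## Preprocessing

All audio is standardized to 8 kHz / 16-bit before anything else
(`standardize()`): high sample rates add cost but little information
for tones under ~1.5 kHz, and the target deployment is low-power
hardware. Resampling is polyphase and anti-aliased (via
`signal::resample`); naive decimation would alias wingbeat harmonics.
The 16-bit depth is simulated by rounding amplitudes to a $2^{-15}$
grid while keeping real-valued storage, which preserves the bit-depth
semantics without a second on-disk format. A useful side effect is that
sums and differences of grid values are exact in double precision, so
dual-microphone subtraction of a unit-gain overlay recovers the clean
signal bit-exactly.

Recordings are peak-normalized group-wise (`normalize_group()`):
globally when one recording setup produced the whole collection, or
per species when sources are heterogeneous, so each group uses the full
16-bit range without clipping.

Epoching (`segment_epochs()`) slides a 300-ms window with 150-ms
overlap (2400 samples, hop 1200 at 8 kHz). A trailing partial window is
dropped, not padded: the network input length is a hard constraint, and
padding would dilute real signal with silence. Epoch counts follow
`floor((n - 2400) / 1200) + 1`.

## Training-time augmentation

Each training pass regenerates every example through
`compose_augmentations()`, in this order:

| operator | parameter | default | units |
|---|---|---|---|
| circular time shift | max shift fraction | 0.10 (±240 samples) | fraction of epoch |
| wingbeat gain | $G$ range | $[1, 2]$, uniform | dimensionless |
| environmental-noise overlay | clean-pass probability | 0.10 | probability |
| Gaussian sensor noise | factor range | $[0.001, 0.01]$, uniform | amplitude |
| amplitude variation | factor range | $[1/4, 4]$, log-uniform | dimensionless (±12 dB) |

The gain multiplies the wingbeat strictly *before* noise addition (it
models mosquito-to-microphone distance), while the final amplitude
factor scales the finished mix (it models overall recording level);
the two have distinct roles and are never merged. With probability 0.10
an epoch skips the overlay entirely and stays clean, so the model does
not overfit to the presence of noise; consequently 90% of each
training pass carries background noise.

Three choices here were genuinely open and are fixed as follows:

- **Amplitude factor is log-uniform**, not linear-uniform: the stated
  range is symmetric in decibels ($20\log_{10} 4 \approx 12.04$,
  rounding to the nominal ±12 dB), and only a log-uniform draw makes
  the dB offset uniform and symmetric.
- **Time shift is circular** rather than zero-padded: it preserves the
  sample multiset and hence waveform energy, and a periodic wingbeat is
  nearly invariant to rotation, so no artificial silence enters.
- **Gaussian noise is added after the environmental overlay**: it
  models sensor/quantization noise, which is present in every recording
  chain regardless of the acoustic scene; the amplitude factor then
  scales the whole mix.

Reproducibility: each (training pass, example) pair gets its own
deterministic draw stream derived from the augmentation seed, so runs
are bit-reproducible while every pass still sees fresh variants.

## The classifier

The network consumes a raw 2400-sample epoch and outputs a softmax
probability vector over the classes (8 = four species × two sexes, with
the fixed alphabetical index: *Ae. aegypti* F=0, M=1; *Ae. albopictus*
F=2, M=3; *An. dirus* F=4, M=5; *Cx. quinquefasciatus* F=6, M=7).

The structure is fixed: a frontend of **three strided 1-D
convolutions**, then **two blocks of 1-D convolution + max pooling**,
then **two fully-connected layers** and the softmax. The strided
frontend performs *learnable* temporal downsampling — in contrast to
summarizing windows by their maximum, the filters can learn
frequency-selective decimation. The per-layer hyperparameters are
configurable (`model_config()`); the defaults are

- frontend: 16 filters × kernel 8 stride 4, 16 × 8 / 4, 32 × 4 / 2
  (valid padding), taking 2400 → 599 → 148 → 73 positions;
- blocks: 32 × 3 and 64 × 3 ("same" padding, stride 1) each followed by
  pool 2, taking 73 → 36 → 18 positions;
- dense head: 1152 → 64 → 32 → `num_class`, ReLU activations,
  about 9 × 10⁴ parameters in total.

These defaults were chosen to satisfy the layer-count structure, keep
the parameter count small enough for CPU training, and pass the
parameter-recovery experiments below; they are deliberately exposed
rather than baked in, since different class counts or sample rates
warrant different geometry. Weights use seeded He-scaled normal
initialization, so a configuration plus seed fully determines the
initial model. Convolution and pooling (forward and backward) run in
compiled code; gradients are verified against central finite
differences in the test suite.

Training (`train()`) minimizes weighted cross-entropy — class weights
proportional to inverse class frequency, normalized to mean 1 — with
Adam (default learning rate 1e-4, up to 1000 passes, batch 128, all
configurable). After every pass the selection metric is computed on the
validation set and the best pass's weights are returned.

Numerical choices: the selection metric defaults to macro F1 (the
protocol's headline metric alongside accuracy, and robust to
imbalance; accuracy and validation loss are also supported since the
choice is not fundamental). Ties on the validation metric break toward
the pass with lower training loss, so a small validation set that
saturates early still tracks continuing optimization. A non-finite
training loss raises an immediate divergence error rather than
continuing silently. `classify()` breaks exact probability ties toward
the lowest class index.

## Evaluation protocol

`stratified_chrono_kfold()` orders each class's epochs by recording
timestamp (ties broken by source id) and cuts them into k contiguous
parts; fold i tests on part i of every class, one of the remaining
parts (cyclically the next) validates, and the rest train. Chronology
prevents temporal leakage: overlapping epochs of one recording, or
recordings made minutes apart, never straddle the train/test boundary.
The split is enforced at the *source-recording* level — a recording's
epochs move as a unit. When recordings contribute several epochs this
makes exactly-equal part sizes impossible; the partition then
equalizes epoch counts as far as recording granularity allows. (With
one epoch per recording, part sizes differ by at most one, which is
property-tested.)

Noisy test sets (`build_noisy_eval_set()`) pair every clean test epoch
with one overlaid copy at a fixed gain, keeping the clean original, so
the test set doubles and contains wingbeats both with and without
noise — realistic, and a check against overfitting to noise. The three
per-gain evaluations (G = 1, 1.5, 2) are built and run independently
and their fold-level predictions concatenated (`crossval()`). Noise
segments are drawn without replacement from the pool's window-aligned
segments when the pool is large enough, otherwise with replacement and
a warning — field noise pools are often only minutes long. Train,
validation and test noise pools must not share recordings.

`eval_report()` computes the C × C confusion matrix, per-class
one-vs-rest precision/recall/F1, $ACC = \sum_c TP_c / N$ and
$MF1 = \sum_c F1_c / C$. A class absent from both truth and predictions
contributes F1 = 0 and **stays in the macro average** — evaluation sets
genuinely missing a class should be visible in the headline number, not
silently renormalized. Degenerate 0/0 precision or recall is defined
as 0.

`mann_whitney_compare()` tests one-sidedly whether run B's per-fold
metric values are shifted above run A's: exact enumeration of the null
distribution when the combined sample size is ≤ 20 and untied, the
normal approximation with midrank tie correction otherwise, α = 0.05.
Random over-sampling (`random_oversample()`) duplicates examples
uniformly within each (dataset, class) group up to the dataset's
largest class count, before heterogeneous datasets are merged.

## The synthetic generator

`synth_wingbeat()` emulates the features of flight tones that matter to
this pipeline: a harmonic stack (default 3 harmonics, geometric
roll-off 0.55) on a fundamental that wanders slowly around the species
mean (mean-reverting AR(1) with ~50 ms time constant, clamped to
±10 Hz) with slow amplitude modulation (depth 0.2, 0.5–2 Hz) — "a
relatively steady, harmonic sound". Profiles whose harmonics would
alias at 8 kHz are rejected. `synth_noise()` produces the four noise
characters seen around traps: impulsive clicks with decay tails, tonal
complexes at low non-wingbeat fundamentals, broadband smoothed noise,
and fan noise (steady low tonal complex plus broadband floor).

The default 8-class bank spans 350–750 Hz with sex modeled as an upward
within-species offset (males beat faster) and deliberate overlap
between adjacent species — the task should be nontrivial, as real
species ranges overlap. Only the female *Ae. aegypti* fundamental
(512 Hz) is anchored to a published observation; the rest are modeling
choices, not biological claims.

What the generator does **not** emulate: room acoustics and
reverberation, microphone transfer functions, multiple simultaneous
mosquitoes, and the dependence of wingbeat frequency on temperature,
humidity and age. Passing the synthetic end-to-end tests therefore
shows that the pipeline is *correct* (it can recover known separable
structure, noise augmentation helps under the stated noise model, and
performance is stable across gains); it does not certify any particular
accuracy on field recordings, whose variability is far richer.

## Scaled-down experiment sizes

The end-to-end checks in the test suite use a 4-class synthetic dataset
with 200 epochs per class, 50 training passes for clean parameter
recovery and 40 for the noise-robustness comparison, at learning rate
1e-3. These sizes are the package's own choice of a desk-scale
experiment: large enough that a correctly implemented pipeline
separates the classes nearly perfectly and that the directional
noise-augmentation comparison is stable under its fixed seeds, small
enough to run routinely. The 1e-3 learning rate compensates the
compressed schedule — the 1e-4 default is calibrated to thousand-pass
training runs, and a 20-fold shorter run takes proportionally larger
steps.

## Known limitations

- The CNN trains on a single CPU thread; thousand-pass runs on datasets
  of real-world size (10⁴–10⁵ epochs) are feasible but slow. The
  architecture is small by design; no GPU path is provided.
- Wingbeat-event detection in long field recordings is out of scope:
  inputs are assumed to be pre-extracted wingbeat periods.
- Stereo/multi-channel audio is rejected rather than downmixed, and
  only 16/24-bit PCM WAV is read, 16-bit written.
- Upsampling is unsupported: recordings below 8 kHz cannot be
  standardized (recordings already at 8 kHz pass through unchanged
  except quantization).
- The Mann-Whitney comparison assumes independent per-fold metrics;
  folds of one cross-validation share training data, so as in the
  source protocol the test is indicative rather than strictly valid.
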