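---
title: "Differential-entropy features and the dual spatial-temporal transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-entropy features and the dual spatial-temporal transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstt)
```

## The problem

Affective brain-computer interfaces try to decode a person's emotional
state from scalp EEG. The most reliable correlates of emotion in EEG are
frequency-domain: the distribution of signal power across the canonical
rhythms (delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz,
gamma 31-50 Hz) shifts with affective state. This package implements a
complete decoding pipeline around that observation: band-wise
differential-entropy (DE) features computed per second and per channel, and
a classifier that models the two structures those features live on — the
spatial layout across electrodes and the temporal evolution across
seconds — with two separate transformer encoders.

## Differential-entropy features

For a band-limited EEG segment that is approximately Gaussian with variance
$\sigma^2$, the differential entropy

$$h = -\int p(x)\log p(x)\,dx = \tfrac{1}{2}\log(2\pi e \sigma^2)$$

is a monotone log transform of band power. We estimate $\sigma^2$ per 1-s
epoch, channel and band with a single Hann-windowed FFT over the epoch (a
one-frame short-time Fourier transform): squared magnitudes are summed over
the two-sided bins whose folded frequency lies in the closed band interval
and normalized by the window energy, so that for band-limited unit-variance
noise the estimate has expectation 1. Natural logarithms are used
throughout; DE is reported in nats. `de_from_power()` floors the variance
at $10^{-12}\ \mu V^2$ so silent channels stay finite.

Two consequences the test-suite exploits: scaling an epoch by $a$ shifts
every DE value by exactly $\log a^2$, and a class that scales the standard
deviation of a band by $1+e$ shifts that band's DE by exactly
$\log(1+e)$ — any fixed multiplicative capture loss of the estimator (band
edges, window leakage) cancels in such differences.

The per-second features $X \in \mathbb{R}^{N\times C\times F}$ (frames,
channels, bands; $F = 5$) are cut into overlapping windows of $T = 10$
consecutive frames, stride 1 by default. Windows never cross trial
boundaries: labels are per-trial, and a window straddling two stimuli would
have no well-defined label. Features are z-scored per (channel, band) cell
with statistics computed on the *training* windows only; the same affine
transform is then applied to the test set. Standard deviations below
$10^{-8}$ are replaced by 1, so constant cells map to zero.

## The classifier

Each window $x \in \mathbb{R}^{T\times C\times F}$ passes through:

1. a linear projection $P \in \mathbb{R}^{F\times D}$ of the band axis to
   $D$ embedding dimensions, plus a learnable spatial position encoding
   $E_{SPos} \in \mathbb{R}^{C\times D}$ — each channel becomes one token;
2. a **spatial encoder**: $L$ pre-norm transformer blocks applied to the
   $C$ channel tokens of every frame, with weights shared across frames.
   Self-attention is $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with $H$
   heads of width $d_k = D/H$;
3. mean pooling over channel tokens, giving one token per frame;
4. a **temporal encoder**: a learnable position encoding
   $E_{TPos} \in \mathbb{R}^{T\times D}$ plus $L$ more blocks over the $T$
   frame tokens;
5. mean pooling over frames, layer normalization, and a linear head
   producing $K$ logits, trained with mean cross-entropy
   $\mathcal{L} = -\frac1N\sum_n\sum_k y_{nk}\log \hat y_{nk}$.

Both position tables are initialized from the classical sinusoidal formula
$\big(\sin(p/10000^{2i/D}), \cos(p/10000^{2i/D})\big)$ and learned
thereafter — "learnable sine-cosine" read as sinusoidal initialization with
gradient updates, which honors both words. With $E_{SPos}$ zeroed the
spatial encoder is exactly channel-permutation equivariant (and the rest of
the network permutation invariant); enabling the table is what lets the
model distinguish electrodes. The test suite checks both directions.

### Architecture defaults, and a conflict

The reference description of this architecture is internally inconsistent:
it states in one place 8 heads with hidden dimension 16 and four
transformer modules, and in another $L = 6$ blocks with $D = 32$ and
$H = 6$ — but 32 is not divisible by 6, which scaled dot-product attention
requires. We default to $L = 6$, $D = 32$, $H = 8$ (divisible), all
configurable through `stt_config()`. Choices the source leaves open, made
here as design decisions:

* **Pre-norm residuals** (`x + MHA(LN(x))`, then `+ MLP(LN(.))`) — the
  standard stable arrangement for small-data training.
* **MLP**: two linear layers with exact GELU ($x\,\Phi(x)$), hidden width
  `mlp_ratio` $\times D$ with `mlp_ratio = 2` — compact at $D = 32$.
* **Pooling** between and after encoders: parameter-free mean pooling over
  tokens (no class token appears in the source description).
* **Dropout** 0.1 on attention and MLP branch outputs during training.
* **Output shape**: logits are $N \times K$; a stated $C \times K$ output
  is treated as a typo.

### Optimization

AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) with
initial learning rate $2\times10^{-4}$, exponential decay $0.98$ per epoch
(epoch 0 trains at the initial rate), decoupled weight decay $0.1$, batch
size 128, 50 epochs by default. Weight decay applies to weight matrices
only — not biases, layer-norm parameters, or the position tables. The
epoch count is a package default (none is stated in the source); the state
with the lowest mean training loss is kept, and no validation split is
carved out because none is described.

Training is fully deterministic given `rng_seed`: initialization, epoch
shuffling and dropout masks all derive from one seed. The mini-batch step
runs as a single fused C++ routine; an R-level reference implementation of
the identical forward/backward computation is retained, and a test asserts
that the two agree to below $10^{-12}$ in loss and in every gradient.

## Evaluation protocol

Decoding is *subject-dependent*: one model per recording session. Trials
are split by recording-order prefix — first 9 of 15 for training in the
three-class layout, first 6 of 8 in the two-class layout — mirroring the
standard split for this task, and the class-interleaved trial order keeps
both partitions balanced. Windows are assigned to partitions by their
source trial, never individually, so overlapping windows cannot leak
across the boundary; the normalizer is fitted on training windows only
(a test corrupts the test trials and asserts the fitted model is
bit-identical). Reported metrics: accuracy (%), macro-averaged F1 (%) —
the unweighted mean of per-class F1, chosen because the prefix split can
leave mild class imbalance in the test partition — per-class F1, and the
$K \times K$ confusion matrix with rows as true classes. Session results
are aggregated as mean ± sd.

## The synthetic data generator

No real EEG ships with the package; every claim the tests make is measured
on synthetic sessions with *planted* ground truth. A session is a sequence
of trials; each trial is a sum over bands of FIR band-limited Gaussian
noise whose per-channel standard deviation is set by the class profile,
plus broadband Gaussian noise. The band component is rescaled to its target
standard deviation after filtering, so the planted variance — and therefore
the planted DE — is exact by construction regardless of filter gain.
`make_default_profiles(n_classes, n_channels, effect)` gives every class a
1-µV baseline in all cells and scales one distinct (band, channel-chunk)
block per class by $1 + \mathrm{effect}$, so the expected between-class DE
contrast in that block is $\log(1 + \mathrm{effect})$.

Defaults: 8 channels, 128 Hz, 5 trials per class (a 15-trial three-class
session), 20-s trials, broadband noise 0.2 µV, class-interleaved trial
order, per-trial seeds derived as master seed + trial index. The 20-s
default keeps a full five-session protocol run compact (11 windows per
trial at $T = 10$) while remaining comfortably decodable; DE-calibration
checks, where the variance of the 1-s spectral estimate matters, use 60-s
trials explicitly. The generator deliberately omits blinks, EMG, volume
conduction and within-trial nonstationarity — so a passing test suite
demonstrates the pipeline's correctness and sensitivity to band-power
structure, not robustness to real-world artifacts.

```{r generator-example, eval = FALSE}
profiles <- make_default_profiles(n_classes = 3, n_channels = 8, effect = 1)
spec <- synthetic_spec(profiles, rng_seed = 1)
session <- synthesize_session(spec)
features <- session_to_features(session)
result <- run_subject_dependent(list(features), n_train = 9, n_test = 6)
result
```

## Numerical choices and degenerate inputs

* Band power uses closed band intervals on integer-Hz bins; the DE
  contrasts the pipeline is judged on are differences of log power and are
  invariant to the bin-edge convention.
* Zero-phase (forward-backward) FIR filtering everywhere a filter appears,
  so epoch boundaries are not latency-shifted; the squared magnitude
  response is accounted for in the filter-quality tests.
* Amplitude rejection is a pure ±100 µV rule per 1-s epoch — the printed
  threshold, automated; no visual inspection step and no ICA (out of
  scope; its removal is the one deliberate preprocessing simplification).
* Epochs are trial-aware; trailing partial seconds of a trial are dropped.
* Trials shorter than $T$ frames contribute no windows; an empty training
  partition, a single-class training set, or an unknown test label raise
  explicit validation errors rather than producing silent results.
* EDF export rounds each channel's physical range outward to two decimals
  so the header scaling a reader recovers matches the scaling used when
  writing; round-trip error is bounded by the 16-bit quantization step.

## Problem sizes used by the checks

The end-to-end checks train 5 synthetic three-class sessions (15 trials of
20 s each) for 50 epochs at the default architecture, twice (once for the
planted effect, once for a null-effect control at chance level), plus an
identical-seed repeat that must reproduce every metric bit-for-bit. These
sizes are the package's chosen desk-scale study conditions; the same code
paths accept arbitrarily longer sessions.

## Known limitations

* The synthetic generator's stationary Gaussian bands are far simpler than
  real EEG; results on it say nothing about cross-subject transfer or
  artifact robustness.
* DE assumes per-band Gaussianity; for strongly non-Gaussian signals the
  closed form is only an approximation to the true entropy.
* The model is trained from scratch per session on minutes of data;
  no pretraining or transfer machinery is included.
* Delta-band (1-3 Hz) DE computed after a 4-47 Hz band-pass measures
  residual stop-band energy; when replicating that preprocessing either
  interpret the delta column accordingly or drop it.
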