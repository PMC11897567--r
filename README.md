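# eegstt

Emotion decoding from multichannel EEG with differential-entropy band
features and a dual spatial-temporal transformer, in R.

## What this is for

EEG correlates of emotion are strongest in the frequency domain: the
power carried by the canonical rhythms (δ 1–3, θ 4–7, α 8–13, β 14–30,
γ 31–50 Hz) shifts with affective state. For a band-limited,
approximately Gaussian EEG segment of variance σ², the differential
entropy

> DE = ½ log(2π e σ²)   (nats)

is a log transform of band power and is the standard per-second,
per-channel, per-band feature for this task. `eegstt` implements the full
path from raw recordings to per-subject decoding metrics:

1. **Preprocessing** — polyphase resampling (e.g. 512 → 128 Hz), mastoid
   re-referencing, zero-phase FIR band-pass (default 4–47 Hz), 1-s
   epoching per trial, ±100 µV amplitude artifact rejection.
2. **Features** — Hann-windowed FFT band power per 1-s epoch →
   DE tensor `X ∈ ℝ^{N×C×F}` (frames × channels × 5 bands) → overlapping
   windows of T = 10 frames → per-(channel, band) z-scoring with
   training-set statistics.
3. **Model** — channel tokens (linear projection of the band axis to
   D = 32 plus a learnable sinusoidally-initialized spatial position
   encoding) → L = 6 pre-norm transformer blocks over channels per frame →
   mean-pool → temporal position encoding → 6 blocks over the T frames →
   mean-pool → layer norm → linear head; multi-head scaled dot-product
   attention, Attention(Q,K,V) = softmax(QKᵀ/√d_k)V, H = 8 heads.
   Trained with cross-entropy, AdamW (lr 2e-4, exp. decay 0.98/epoch,
   weight decay 0.1, batch 128). Forward/backward are hand-derived; the
   production step is a fused C++ kernel verified against an R reference
   implementation to 1e-12.
4. **Protocol** — subject-dependent evaluation: one model per session,
   trial-prefix splits (9/6 of 15 trials for three classes, 6/2 of 8 for
   two), accuracy / macro-F1 / confusion matrices, mean ± sd across
   sessions.
5. **Synthetic data** — labeled sessions of FIR band-limited Gaussian EEG
   whose classes differ by planted per-band, per-channel variance, so the
   expected DE contrast between classes is exactly log(1 + effect).

## Worked example

Simulate one three-class session with a planted effect of 1.0, run the
subject-dependent protocol, and inspect the result:

```r
library(eegstt)

profiles <- make_default_profiles(n_classes = 3, n_channels = 8, effect = 1)
spec     <- synthetic_spec(profiles, rng_seed = 7)
session  <- session_to_features(synthesize_session(spec))
result   <- run_subject_dependent(list(session), n_train = 9, n_test = 6,
                                  train_cfg = train_config(rng_seed = 11))
result
#> <protocol_result> 1 session(s): accuracy 96.97 +/- 0.00 %, macro-F1 96.96 +/- 0.00 %
result$per_session[[1]]$confusion
#>         predicted
#> truth    class1 class2 class3
#>   class1     20      0      2
#>   class2      0     22      0
#>   class3      0      0     22
```

Each of the 6 held-out trials of 20 s contributes 11 overlapping T = 10
windows (66 test windows); 64 are classified correctly.

The planted effect scales one (band, channel-block) per class by 2× in
standard deviation, i.e. a DE contrast of log 2 ≈ 0.693 nats; with 20-s
trials the model recovers the three classes from the 6 held-out trials
almost perfectly, while `effect = 0` collapses the classes and accuracy
drops to chance (≈ 33%).

A command-line interface wraps the same stages
(`inst/cli/eegstt.R simulate | preprocess | features | protocol`); every
run writes a `manifest.json` with the resolved configuration, seed and
output checksums.

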