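# bleatnet

Classifying the age group and sex of giant pandas (*Ailuropoda
melanoleuca*) from their vocalizations.

Panda bleats are informative signals: source features (the fundamental
frequency F0) track age and body size, while filter features (vocal-tract
formants) track sex. `bleatnet` is an R implementation of a complete
bioacoustic recognition pipeline built on that premise, aimed at
conservation bioacousticians and method developers who need a tested,
reproducible reference for small, imbalanced call datasets:

* **Audio front end** — PCM WAV I/O (8/16/24/32-bit integer and float),
  mono mixdown, polyphase resampling to 44,100 Hz, non-overlapping 2-s
  segmentation, background-noise mixing at a target SNR.
* **Features** — MFCC matrices: centered 1024-point framing with hop 512,
  Hamming window, FFT power spectrum, 64 triangular mel filters
  (HTK scale), log energies zero-padded to 173 frames, orthonormal
  DCT-II. Every segment becomes the fixed network input, a
  `173 x 64 (x 1)` matrix.
* **Augmentation** — Gaussian noise on the log-mel spectrum and
  SpecAugment frequency/time masks, with per-class replication factors
  (male x6, juvenile x2, adult x1) that balance the classes.
* **Classifier** — a compact CNN with Squeeze-and-Excitation channel
  attention (squeeze: per-channel global average pool; excite: bottleneck
  MLP with sigmoid output; rescale: channel-wise multiply), trained with
  Adam (batch 32, lr 1e-3) under **focal loss**

  `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)`

  with class-balanced `alpha_t` and `gamma = 2`, or cross entropy in the
  baseline arms. The hot path is compiled (RcppArmadillo) and fully
  deterministic under a seed.
* **Evaluation** — the individual-exclusive protocol: per repetition,
  4 held-out individuals form the test set (copied round-robin or
  subsampled to exactly 100 segments), training subsampled to exactly 540
  segments from the remaining individuals; precision/recall/F1
  (`F1 = 2PR/(P+R)`, zero when tp = 0) reported as mean ± sd across 10
  repetitions. Experiment arms: E1 (pooled split), E2A (exclusive), E2B
  (+augmentation), E2C (+focal loss), plus a 540→720 training-size sweep.
* **Synthetic corpus** — since the motivating recordings are available
  only on request, a source-filter call generator emulates the study
  population (8 juvenile females, 3 juvenile males, 13 adult females, 4
  adult males; females vocalizing ~7x more than males) with
  class-dependent F0 and formants, per-individual random effects and
  group-dependent noise. A `separation` knob scales all class differences;
  0 is an exact null model.

## Worked example

Generate a small synthetic corpus, featurize it, and run the full E2C
pipeline (augmentation + focal loss, individual-exclusive splits) on the
age task:

```r
library(bleatnet)

cfg <- list(
  seed = 7L,
  out_dir = file.path(tempdir(), "demo"),
  generate = list(
    group_sizes = list(juvenile_female = 3L, juvenile_male = 2L,
                       adult_female = 4L, adult_male = 3L),
    calls_per_individual = c(12L, 14L),
    separation = 1),
  model = list(profile = "test"),
  run = list(n_reps = 3L, n_test = 40L, n_train = 100L))

cmdGenerate(cfg)
cmdFeaturize(cfg)
res <- cmdRun(cfg, arm = "E2C", task = "age")
res
```

```
[generate] 121 calls from 12 individuals -> /tmp/.../demo/dataset (seed 108)
[featurize] 197 segments -> /tmp/.../demo/features.rds
[run E2C/age] F1 1.0000 +/- 0.0000 (seed 308)
EvalResult [E2C/age], 3 repetitions
  precision 1.0000 +/- 0.0000
  recall    1.0000 +/- 0.0000
  F1        1.0000 +/- 0.0000
```

At `separation = 1` the planted age structure (juvenile F0 ≈ 600 Hz vs
adult ≈ 250 Hz) is fully recoverable, so the pipeline classifies every
held-out individual's segments correctly: precision, recall and F1 are
all 1 with zero spread across repetitions. Lower the `separation` (or
switch to `task = "sex"`, where the planted differences are deliberately
weaker) to see the scores degrade gracefully; at `separation = 0` the
corpus carries no class information at all and scores drop to chance.
Per-repetition metrics land in `<out_dir>/results/*_metrics.csv` with a
JSON mean/sd summary alongside. A command-line wrapper over the same
functions ships in `inst/scripts/bleatnet.R`.

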