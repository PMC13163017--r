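---
title: "Methods: lightweight acoustic classification of goat vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight acoustic classification of goat vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Continuous, non-invasive welfare monitoring of dairy goats can be built on
their vocalizations: bleats carry information about arousal (fundamental
frequency rises with vocal-fold tension), valence, and social context
(mother–kid recognition rides on individual timbral signatures). The
dominant machine-listening approach — convolutional networks over 2-D
spectrogram images — is accurate but too heavy for the low-power edge
hardware that on-farm deployment requires. `bleatr` implements the
lightweight alternative: a fixed 156-descriptor 1-D feature vector feeding
small tabular classifiers, with the compact multilayer perceptron (MLP) as
the deployment model.

The pipeline is: WAV ingestion → resampling (22,050 Hz) → duration
standardization (2 s) → feature extraction → stratified 80/20 split →
SMOTE balancing of the training partition → z-score standardization →
optional importance-threshold feature selection → model training →
weighted evaluation → latency/footprint benchmark.

## The feature vector

All short-time analysis uses a periodic Hann window of 2048 samples with a
512-sample hop, centered frames, reflection padding. The canonical
(`table1`) schema has 156 entries:

| block | count | descriptors |
|---|---|---|
| temporal/energy | 5 | RMS mean/std, ZCR mean/std, autocorrelation peak |
| time evolution | 3 | spectral flux mean/std, temporal centroid |
| MFCC | 40 | per-coefficient means (128-band Slaney mel, DCT-II) |
| ΔMFCC | 40 | per-coefficient means of the 9-frame regression slope |
| ΔΔMFCC | 40 | means of the second derivative |
| spectral shape | 20 | centroid, bandwidth, 85% roll-off (mean/std each), 7-band contrast (mean + std per band) |
| complexity | 2 | spectral entropy (bits), spectral flatness |
| bioacoustic | 2 | Acoustic Complexity Index, Bioacoustic Index (2–8 kHz) |
| pitch | 4 | F0 mean, max, std, least-squares slope (pYIN) |

The `extended` schema (276 entries) appends the per-coefficient standard
deviations of the three cepstral blocks, so importance tokens such as
`mfcc_std_5` exist as first-class features. The canonical mode keeps the
40 per-coefficient means per cepstral block — the only allocation under
which the block counts sum to 156 — and places the std statistics in
`extended`. Both modes are CLI-selectable.

## Numerical choices that matter

* **Framing.** STFT frames are centered with *reflection* padding.
  Zero padding would place a hard signal onset at the center of the edge
  windows (where the Hann taper is maximal) and splatter broadband energy
  at roughly −66 dB — enough to contaminate leakage-level descriptors.
* **Time-domain statistics** (RMS, ZCR) use non-centered, fully populated
  frames so a constant signal has exactly zero frame-to-frame dispersion.
* **MFCC dynamic range.** Log-mel power is clamped 80 dB below the clip
  maximum (the standard `top_db` convention). Besides matching the
  dominant toolkits, the clamp makes two properties exact: a stationary
  tone yields frame-invariant coefficients, and a global gain change moves
  only coefficient 0.
* **Bioacoustic Index** uses the classic definition — area of the
  time-averaged dB spectrum (reference = max, floor −80 dB) above the band
  minimum within 2–8 kHz, in dB·kHz. Frames whose window overlaps the
  reflection padding are excluded from the average; their crease artifact
  otherwise leaks artificial in-band energy on purely low-frequency clips.
* **ACI** uses a single temporal block per 2-s clip: applied to an
  isolated call it measures within-call amplitude-modulation chaos, and
  the ratio form makes it gain-invariant.
* **pYIN.** Difference function over a 1024-sample integration window,
  cumulative-mean normalization, parabolic trough interpolation, a
  Beta(2, 18) prior over YIN thresholds, and Viterbi decoding over a
  12-bins-per-octave grid (65–2093 Hz) plus an unvoiced state. The
  unvoiced observation mass is spread as if over the reference 10-cent
  grid so the voiced/unvoiced prior odds are independent of the coarser
  decoding grid; pitch precision comes from the parabolic interpolation,
  not the grid. Voicing collapses once the aperiodic power fraction
  reaches roughly 20–30%, which is the canonical behavior of the
  threshold prior.
* **Sentinels.** Silent frames contribute 0 to centroid/bandwidth/
  roll-off; a silent clip's temporal centroid is the clip midpoint; F0
  statistics are 0 when fewer than two frames are voiced; 0/0 per-class
  metrics are 0. All are logged, and extraction guarantees a finite
  vector.
* **Population standard deviation (ddof 0)** everywhere, matching the
  z-score definition used for standardization (`z = (x − μ)/σ` with μ, σ
  from the training partition only; zero-variance features map to 0).
* **Stratified split** allocates per-class test counts by largest
  remainder targeting `round(n · fraction)`, randomized within class, so
  the 20% share is exact to within one clip per class.
* **SMOTE** uses k = 5 Euclidean same-class neighbors (falling back to
  `n_c − 1` for small classes) and interpolates uniformly on the segment;
  it accepts only the training partition by construction.
* **Feature selection** fits the gradient-boosted ensemble and keeps
  features with split-gain importance at or above the mean — the standard
  select-from-model default. The 54-feature subset reported on the real
  corpus is corpus-specific, not a contract.

## Models

Fourteen families share one `model_spec()`/`train_model()`/`predict()`
surface: the tuned MLP, gradient-boosted trees, random forest, extra
trees, decision tree, AdaBoost (SAMME), k-NN, multinomial logistic, ridge,
LDA, QDA, Gaussian naive Bayes, a one-vs-rest linear SVM, and a majority
baseline. Tree learners are backed by a CART engine in C++ (weighted Gini
or SSE splits, mtry subsampling, Extra-Trees random thresholds); LDA/QDA
come from MASS, k-NN neighbors from FNN, and the penalized linear models
from glmnet. Labels are always ordered alphabetically.

The MLP is the deployment model: hidden layers (256, 128), tanh
activations, softmax output, cross-entropy with L2 penalty 0.001, Adam at
learning rate 0.001, batch 32, early stopping on a 10% stratified
validation split with patience 10, at most 500 epochs. The design
question of whether the deployment model should consume the full
156-vector or a selected subset is resolved in favor of the full vector
by default — the MLP's own L2 regularization handles the dimensionality,
and skipping the selection stage keeps the edge pipeline simpler;
selection remains available via `--select`.

`grid_search_mlp()` implements the exhaustive 3-fold search over the
canonical space (five topologies, relu/tanh, three learning rates, three
batch sizes, four penalties; `default_mlp_grid()`), breaking ties toward
the smaller network and then the lower learning rate. The Bayesian tuner
commonly used for tuning tree models is abstracted as
`tune_spec()`, a pluggable stochastic search that always evaluates the
starting spec and never returns anything worse on CV accuracy; tuning
gains for gradient boosting on this task are marginal, so specialized
optimizer internals are out of scope.

Feature attribution is permutation importance (mean accuracy drop over
seeded shuffles of one column; per-class recall drops on request). Exact
SHAP values are a cited external algorithm, not part of this package's
contract; tree families additionally expose internal gain importance.

## Evaluation

All metrics derive from the confusion matrix with support-weighted
averaging: accuracy, precision, recall, F1, and Cohen's kappa
`K = (Pr(a) − Pr(e))/(1 − Pr(e))` with `Pr(e)` the product-of-marginals
chance agreement. Support weighting makes weighted recall equal accuracy
identically — asserted as a property test rather than treated as a bug.

## The synthetic world

Real corpora of labeled goat vocalizations cannot ship with a package, so
`synth_bleat()` generates class-conditioned calls: an additive harmonic
stack (1/k amplitude decay) with sinusoidal FM, mixed with low-passed
Gaussian noise (−6 dB/octave above 4 kHz) at a class-specific power
ratio, under a smooth random amplitude envelope, at a random onset over a
continuous 15 dB-SNR ambience floor, peak-normalized to 0.9. The eight
default profiles follow the documented spectrogram phenotypes: tonal
ladder-like harmonics for injury (F0 600 Hz, 10 harmonics, 5% noise) and
social isolation; FM-contoured tonal calls for the maternal classes;
broadband profiles for feed distribution, parturition and unknown
visitors; and a hybrid harmonic-plus-noise profile for heat. The
mother–kid reunion and separation profiles are identical except for FM
rate (4 vs 8 Hz), deliberately reproducing the hardest real-world
confusion in miniature.

Within-class realism comes from per-call jitter: duration ±30%, FM depth
±40%, FM rate ±25%, noise ratio ±0.08, plus the stated F0 jitter and a
random onset. Without it every profile is a fixed template and the
end-to-end task saturates at 100% accuracy, which would validate nothing.
With it, the seed-fixed end-to-end run (8 × 60 clips) lands in the low
0.90s with the reunion/separation pair supplying most of the confusion —
a faithful miniature of published results on the public corpus (high-80s
overall accuracy, with the separation class weakest and injury/reunion
strongest).

What the generator does *not* emulate: overlapping simultaneous callers,
reverberation and machinery transients, breed and individual identity
structure, microphone channel effects, and the heavy class imbalance of
real farm recordings (imbalance is available via `n_per_class` but the
acceptance world is balanced). A green end-to-end test therefore
establishes that the pipeline's plumbing, feature code, balancing,
training and evaluation interact correctly on a learnable-but-overlapping
task — not that the accuracy transfers to any real barn.

## Benchmarking

`benchmark_model()` reports median-of-means per-sample latency (with an
adaptive inner loop so sub-resolution models still time measurably) and
the on-disk size of the serialized bundle. Bundles are stored
*uncompressed*: published footprint figures for comparable pipelines
(≈0.6 MB for an MLP, tens of MB for 500-tree forests) are only consistent
with the uncompressed pickle convention, and compression would hide the
memory the artifact occupies once loaded. Absolute numbers are
hardware-dependent report outputs; tests assert only orderings.

## Known limitations

* The pYIN decoding grid is coarse (12 bins/octave); F0 precision relies
  on parabolic interpolation and degrades for strongly modulated calls.
* QDA requires more per-class rows than features and will error on the
  full 156-vector at small n; it is a screening family, not a deployment
  path.
* The linear SVM is a subgradient one-vs-rest implementation adequate for
  screening, not a reference QP solver.
* Latency measurements on shared hardware are noisy; only the footprint
  is deterministic.
* Upsampling to 30,000 Hz is supported (`--rate 30000`) but, as in the
  published protocol it mirrors, adds no information beyond the original recording
  bandwidth.
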