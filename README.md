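# bleatr

Lightweight acoustic classification of goat vocalizations for precision
livestock farming.

Dairy goats vocalize differently in heat, at feed distribution, during
parturition, when injured, when socially isolated, at mother–kid reunion
and separation, and at the presence of unknown visitors. Those
differences are acoustic: arousal raises the fundamental frequency F0
(vocal-fold tension), distress floods tonal bleats with broadband chaos,
and mother–kid recognition rides on fine timbral micro-texture. `bleatr`
turns each 2-second clip into a fixed 156-descriptor feature vector and
classifies it with small tabular models — the deployment model is a
two-hidden-layer perceptron small enough (≈0.6 MB, sub-0.1 ms inference)
for low-power on-farm edge hardware, avoiding the 2-D
spectrogram-image/CNN route entirely.

## The pipeline

```
WAV → resample (22,050 Hz) → standardize (2 s, zero-pad/truncate)
    → 156 features: MFCC/Δ/ΔΔ (40 each, 128-band Slaney mel),
      RMS/ZCR stats, autocorrelation peak, spectral flux + temporal
      centroid, spectral centroid/bandwidth/roll-off, 7-band spectral
      contrast, spectral entropy + flatness, Acoustic Complexity Index,
      Bioacoustic Index (2–8 kHz), pYIN F0 mean/max/std/slope
    → stratified 80/20 split → SMOTE on the training partition
    → z-score (z = (x − μ)/σ, train-fitted) → optional importance-threshold
      feature selection (gradient-boosted gain ≥ mean)
    → classifier → weighted P/R/F1 + Cohen's κ → latency/footprint bench
```

Fourteen model families share one interface (`model_spec()`,
`train_model()`, `predict()`): the MLP (256–128 tanh, Adam 0.001, batch
32, L2 0.001, early stopping patience 10), gradient-boosted trees, random
forest, extra trees, AdaBoost, decision tree, k-NN, logistic, ridge, LDA,
QDA, naive Bayes, linear SVM, and a majority baseline. A class-conditioned
synthetic bleat generator (`synth_bleat()`, `synth_corpus()`) makes every
stage testable without a recorded corpus.

Key quantities, in the field's standard notation:

- z-score: `z = (x − μ)/σ` (μ, σ population statistics of the training
  partition);
- SMOTE: `x_new = x_i + u·(x_nn − x_i)`, `u ~ U(0,1)`, `x_nn` one of the
  k = 5 nearest same-class neighbors;
- Cohen's kappa: `K = (Pr(a) − Pr(e)) / (1 − Pr(e))`;
- ACI: `Σ_k Σ_t |m(t+1,k) − m(t,k)| / Σ_t m(t,k)`;
- Bioacoustic Index: area of the time-averaged dB spectrum above its band
  minimum within 2–8 kHz.

## Worked example

```r
library(bleatr)

corpus   <- synth_corpus(n_per_class = 20L, seed = 42L)
features <- extract_corpus_features(corpus$waves, corpus$labels,
                                    corpus$clip_ids)
result   <- run_training_pipeline(features, family = "mlp", seed = 42L)
print(result$metrics)
```

```
accuracy 0.9062 | weighted P 0.9125 R 0.9062 F1 0.9058 | kappa 0.8929
                         label precision recall    f1 support
1            feed_distribution      0.75   0.75 0.750       4
2                         heat      1.00   1.00 1.000       4
3              injury_or_death      1.00   1.00 1.000       4
4           mother_kid_reunion      1.00   0.75 0.857       4
5        mother_kid_separation      0.80   1.00 0.889       4
6                  parturition      1.00   1.00 1.000       4
7 presence_of_unknown_visitors      0.75   0.75 0.750       4
8             social_isolation      1.00   1.00 1.000       4
```

The error structure mirrors the field's experience: the acutely distinct
classes (injury, isolation, heat) are clean while the maternal
reunion/separation pair — same call type, different context — supplies
the confusion. Feature attribution and the edge benchmark:

```r
Xte <- apply_scaler(result$scaler, features$X[result$split$test, ])
head(permutation_importance(result$model, Xte,
                            features$y[result$split$test],
                            n_repeats = 3L, seed = 1L), 3)
#         feature importance
#  contrast_std_0 0.03125000
#   delta_mean_30 0.01041667
#  delta2_mean_30 0.01041667

benchmark_model(result$model, Xte, repeats = 5L, scaler = result$scaler)
# latency 0.0381 ms/sample (sd 0.0037 over 5 repeats, batch 32); footprint 0.613 MB
```

A footprint in the same 0.6 MB band as published edge-MLP pipelines, an
order of magnitude under a 500-tree forest trained on the same task.

## Command line

```sh
Rscript -e 'bleatr::bleat_cli()' simulate --out corpus --n-per-class 60 --seed 7
Rscript -e 'bleatr::bleat_cli()' extract  --in corpus --out features.csv --schema table1
Rscript -e 'bleatr::bleat_cli()' train    --features features.csv --model mlp \
                                          --smote --seed 7 --out model.bundle \
                                          --metrics metrics.json
Rscript -e 'bleatr::bleat_cli()' evaluate --model model.bundle --features features.csv
Rscript -e 'bleatr::bleat_cli()' bench    --model model.bundle --features features.csv
```

All randomness derives from `--seed`; two runs with the same master seed
produce identical metrics.

## Method details

See `vignettes/bleatr-methods.Rmd` for the model and its assumptions, the
parameters that matter (with defaults and why), what the synthetic
generator does and does not emulate, and every numerical convention
(framing, dynamic-range clamps, sentinels, tie-breaks).
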