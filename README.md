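# asnet

Self-organized deep feature engineering for two-class medical image
classification.

## Scientific problem

Detecting ankylosing spondylitis (AS) on sacroiliac MRI slices is a
two-class image classification problem in which the discriminative signal —
bone-marrow-edema hyperintensity near the sacroiliac joint — is subtle and
training data are scarce. Rather than training a deep network end to end,
this package implements a *feature-engineering* pipeline built on frozen
pretrained convolutional networks: the networks only supply fixed feature
vectors, and all learning happens in feature selection, a minimal-bias
nearest-neighbor classifier, and a self-organized ensemble-selection step.
The same machinery applies to any two-class image (or tabular feature)
problem.

## The pipeline

For a dataset of `n` labeled images:

1. **Extraction.** Six feature matrices `X₁…X₆` are tapped from three
   pretrained backbones (DenseNet-201, ResNet-50, ShuffleNet; one pooled
   and one final-affine layer each), with widths
   1000, 1920, 1000, 2048, 544, 1000.
2. **Selection.** Each matrix is reduced by three filter selectors —
   neighborhood component analysis (NCA), ReliefF, and chi-square — keeping
   the top `k = 272` columns each: 18 selected sets.
3. **Classification.** Each set is classified by 1-NN (Euclidean,
   training-fold z-scoring) under stratified 10-fold cross-validation,
   giving 18 out-of-fold prediction vectors `p₁…p₁₈`.
4. **Iterative majority voting.** The vectors are sorted by accuracy; for
   each prefix size `r ∈ {3,…,18}` the per-sample mode is taken (ties to the
   smallest class code): 16 voted outcomes `v₃…v₁₈`.
5. **Self-organized selection.** The final output is
   `argmax_acc {p₁…p₁₈, v₃…v₁₈}` over all 34 candidates.

Pretrained weights are not bundled and no deep-learning runtime is
required: the default `extractor = "toy"` produces deterministic seeded
stand-in matrices of the exact published widths from classical image
statistics, and externally extracted features can be supplied directly as
matrices or via `read_feature_table()`. See the methods vignette
(`vignettes/methods.Rmd`) for the full model description, parameter
rationale, and a discussion of the selection-before-CV bias inherited from
the original protocol (and the leakage-free `selection_mode = "nested"`
alternative).

## Worked example

```r
library(asnet)

# a seeded two-class phantom dataset written as PNGs in class subdirectories
dir <- file.path(tempdir(), "phantoms")
manifest <- gen_image_dataset(
  fixture_spec(n_per_class = 16, image_size = c(32, 32), delta = 1, seed = 42),
  dir)
print(manifest)

fit <- asnet(manifest, seed = 42)
print(fit)
summary(fit)
```

Output:

```
Dataset manifest: 32 samples, 2 classes
  1 = case: 16 samples
  2 = control: 16 samples
Self-organized deep feature engineering fit
  6 feature matrices x 3 selectors -> 18 prediction vectors; 16 voted outcomes; 34 candidates
  best outcome: densenet201/avg_pool+nca, accuracy 78.13%
Self-organized deep feature engineering fit
  6 feature matrices x 3 selectors -> 18 prediction vectors; 16 voted outcomes; 34 candidates
  best outcome: densenet201/avg_pool+nca, accuracy 78.13%

Candidate outcomes (descending accuracy, top 10):
                       id            type accuracy
 densenet201/avg_pool+nca classifier-wise    78.13
                 voted_r3           voted    75.00
                 voted_r5           voted    75.00
                 voted_r6           voted    75.00
    resnet50/avg_pool+nca classifier-wise    75.00
                 voted_r4           voted    71.88
                 voted_r7           voted    71.88
   densenet201/fc1000+nca classifier-wise    71.88
      resnet50/fc1000+nca classifier-wise    71.88
                 voted_r8           voted    68.75

Accuracy: 78.13%
  case                 recall   62.5%  precision  90.91%  F1  74.07%
  control              recall  93.75%  precision  71.43%  F1  81.08%
```

Further entry points: `run_pipeline(data_dir, out_dir)` writes
`report.json`, `classifier_wise.csv`, and `metrics.csv` in one call;
`predict(fit, new_manifest)` classifies held-out images;
`plot(fit)` draws the 34 candidate accuracies; a command-line wrapper is
installed at `system.file("cli", "asnet.R", package = "asnet")`.

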