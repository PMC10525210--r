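---
title: "Methods: self-organized deep feature engineering for two-class image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-organized deep feature engineering for two-class image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The pipeline addresses two-class medical image classification (the motivating
application is detecting ankylosing spondylitis on sacroiliac MRI slices,
where the discriminative signal is bone-marrow-edema hyperintensity near the
sacroiliac joint). Instead of training a deep network end to end, it treats
frozen pretrained convolutional networks as fixed feature extractors and
pushes all the learning into feature selection, a minimal-bias classifier,
and an ensemble-selection step:

1. **Feature extraction.** Each image is read, resized to 224×224 RGB, and
   passed through three backbones, tapping two layers per backbone:
   DenseNet-201 (final affine output, 1000-d; global average pool, 1920-d),
   ResNet-50 (1000-d; 2048-d), and ShuffleNet (a 544-d internal node and the
   1000-d final affine output). This yields **6 feature matrices** per
   dataset with widths 1000, 1920, 1000, 2048, 544, 1000.
2. **Feature selection.** Each matrix is reduced by three filter selectors —
   neighborhood component analysis (NCA), ReliefF, and chi-square — keeping
   the **272** highest-scoring columns each, giving 18 selected sets.
3. **Classification.** Each selected set is classified by a 1-nearest-neighbor
   classifier (Euclidean distance, features z-scored on the training fold)
   under stratified 10-fold cross-validation, producing 18 out-of-fold
   prediction vectors.
4. **Iterative majority voting (IMV).** The 18 vectors are sorted by accuracy
   (descending, stable); for each prefix size `r` in 3..18 the per-sample
   mode is taken (ties to the smallest class code), giving **16 voted
   outcomes**.
5. **Self-organized selection.** The final output is the maximum-accuracy
   candidate among all 18 + 16 = **34** outcomes, ties preferring voted over
   classifier-wise, then smaller `r`, then earlier index.

`asnet()` is the single fitting entry point; it accepts an image manifest, a
single feature matrix, or a list of matrices, and returns an S3 object with
`print`, `summary`, `plot`, `fitted`, and `predict` methods.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `k` (features kept per selector) | 272 | The published operating point; all registered tap widths (min 544) exceed it. |
| `selectors` | NCA, chi2, ReliefF | The three filter selectors of the original design. |
| `cv` folds | 10, stratified | Standard protocol; stratification keeps both classes in every training fold. |
| `r_min`, `r_max` | 3, 18 | Voting over fewer than 3 vectors is degenerate; 18 is the number of prediction vectors (clamped if fewer). |
| NCA `lambda` | `1/n` | Scales the ridge penalty with the objective, which is a sum over `n` leave-one-out probabilities. |
| NCA `learn_rate` | 0.1, backtracked | Initial step only; backtracking halves on non-improvement, so the result is insensitive to it. |
| ReliefF `k_hits` | 10 | Common ReliefF choice; every class must have more than `k_hits` members. |
| chi2 `n_bins` | 10 | Equal-width binning of continuous activations; zero-count bins are dropped. |
| `selection_mode` | `"full"` | Replicates the published protocol (selection on the full dataset before CV); see the bias discussion below. |

## Numerical choices

- **NCA** is the diagonal-weight variant: `p_ij ∝ exp(−Σ_r w_r² |x_ir − x_jr|)`,
  objective `Σ_i p_i − λ Σ_r w_r²`, full-batch gradient ascent from `w = 1`
  with backtracking line search and a relative-improvement stopping rule
  (`tol = 1e-7`). Scores are the fitted `w_r²`. Features are z-scored
  internally with the population standard deviation. A zero-variance column
  enters the objective only through the penalty, so its optimal weight is
  exactly 0 and it is solved analytically rather than iterated.
- **ReliefF** is the deterministic all-instances form (no random
  subsampling): Manhattan distance on min-max scaled features, `k_hits`
  nearest neighbors per class, misses weighted by `P(class)/(1 − P(own))`,
  final division by `n`. Distance ties break by ascending sample index.
- **1-NN** breaks exact distance ties by the lowest training-row index, and
  the squared-distance scan uses an early-exit accumulation; both are
  checked against a brute-force oracle to 1e-10.
- **Standardization** uses the population standard deviation (divisor `n`);
  constant training columns map to 0 everywhere so degenerate features never
  produce NaN. Per-fold standardization (the default) fits these parameters
  on the training fold only.
- All O(n²·d) kernels (NCA, ReliefF, 1-NN) are implemented in C++ via Rcpp;
  the R-level test oracles are independent transliterations of the
  definitions.
- Reported percentages are rounded half-up to two decimals, matching the
  convention of the published tables; `f1_score()` reproduces the printed
  per-class F1 values from the printed (recall, precision) pairs.

## Feature extraction modes

Pretrained backbone weights are large binary artifacts and are **not
bundled**; no deep-learning runtime is assumed. Three routes exist:

- `extractor = "toy"` (default, fully tested): a deterministic, seeded
  stand-in that computes 52 classical image statistics (moments, a 16-bin
  histogram, 4×4 block means and gradient energies) and projects them
  through a fixed Gaussian matrix to each registered tap width. It preserves
  the pipeline's *shape* (6 matrices of the exact published widths) and is
  sensitive to real image structure, while making no claim to ImageNet
  semantics.
- `extractor = "pretrained"`: raises an actionable error describing how to
  supply real activations.
- `read_feature_table()` / a list of matrices passed to `asnet()`: features
  exported from any external extractor can be used directly.

Image I/O covers PNG, JPEG (via EBImage when installed), uncompressed BMP,
and single-frame uncompressed DICOM (explicit and implicit VR little-endian,
with rescale slope/intercept), the latter two through minimal readers
because no suitable R package is available in the target environment.

## Synthetic fixtures as study conditions

`fixture_spec()` fixes the generator parameters; its defaults (100 samples
per class, 600 features, class shift `delta` expressed in noise standard
deviations, 10% informative columns) are the study conditions used by the
tests and the acceptance script, not tuning knobs. `gen_feature_bank()`
draws independent matrices sharing one label vector; `gen_image_dataset()`
writes seeded two-class phantom images (smooth background, a dark joint
line, and — for the case class — hyperintense Gaussian blobs emulating
bone-marrow edema) into class subdirectories. Phantoms are byte-identical
under a fixed seed. They are deliberately simple: they test the machinery's
statistical behavior (signal recovery, null calibration, determinism), not
clinical performance.

## Selection bias: full versus nested mode

The published protocol selects features on the **full dataset** before
cross-validation. This leaks label information into the CV estimate: with
many features and a best-of-34 maximization on top, the null expectation is
far above chance. At the default fixture scale (200 samples, 600 features
per matrix, 272 kept, `delta = 0`) the full-mode best-of-34 accuracy is
about 0.91 even though the labels are pure noise. The package therefore
also provides `selection_mode = "nested"`, which re-ranks and re-selects
inside every training fold; at smaller scales the test suite shows it
calibrates to chance. The default remains `"full"` for fidelity to the
original protocol, and the documentation — not a silent change — carries
the warning.

## Problem sizes and runtime

The unit suite exercises 12–50 samples and up to 60 features; the
acceptance checks run the full default geometry (6 matrices, 200 samples,
600 features, `k = 272`) in roughly 10 s per fit on one CPU, and a full
image-to-report run on 32 phantoms in a few seconds. `scripts/acceptance.R`
writes the main computed quantities (structural counts, separable and null
best accuracies, oracle deviations, selector sanity values, F1 identities)
to JSON for any seed.

## Limitations

- Toy-extractor accuracies are not comparable to published clinical
  accuracies; reproducing those requires the private MRI dataset and real
  backbone activations.
- ShuffleNet's internal 544-d tap is identified positionally in the backbone
  registry; with real extractors the user must export the matching layer.
- The DICOM reader intentionally supports only single-frame, uncompressed,
  little-endian files.
- `predict()` on new data requires `selection_mode = "full"` (nested mode
  has no single selected feature set to reuse).
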