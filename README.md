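# swldanet

Multi-class classification of 2-D grayscale images — in the spirit of
severity grading of brain MRI slices (non / very-mild / mild / moderate
dementia) — with a hybrid pipeline:

1. **Mean-filter preprocessing.** Every pixel is replaced by the mean of its
   3×3 neighborhood (the uniform 1/9 mask), with replicate padding at the
   borders, suppressing pixel-level noise before feature extraction.
2. **Eigenimage (PCA) features.** Flattened training images `x_i ∈ R^D` are
   centered and the top *K* eigenvectors `v_1 … v_K` of the pixel covariance
   `S = (n−1)^{-1} Σ (x_i − x̄)(x_i − x̄)'` are computed through a
   rank-reduced SVD (the D×D covariance is never formed). Images are
   represented by their scores `c_ik = (x_i − x̄)' v_k`.
3. **Stepwise linear discriminant analysis (SWLDA).** Class labels are
   indicator-coded and regressed on the scores; the discriminant weights
   solve `L̂ = (M'M)^{-1} M'y`. Features are selected stepwise: forward
   entry admits the candidate with the smallest partial-*F* p-value below
   `α_enter = 0.35`, backward elimination drops the selected feature with
   the largest p-value above `α_remove = 0.40`, up to a cap of 125 features.
   The partial *F* comes from the Wilks'-lambda ratio of residual scatter
   determinants with and without the candidate,
   `Λ = det(E_full)/det(E_reduced)`, converted exactly (single-df
   hypothesis) to `F = ((1−Λ)/Λ)·(ν_E − m + 1)/m` with `m = G − 1` indicator
   responses; for two classes this is the squared partial *t*.
4. **Dense network classifier.** A one-hidden-layer network (512 ReLU units,
   inverted dropout 0.5, softmax output) trained with Adam (lr 0.001, batch
   32, 100 epochs, validation split 0.25) and categorical cross-entropy.
   For 100 inputs, 512 hidden units and 4 classes the parameter count is
   `100·512 + 512 = 51,712` plus `512·4 + 4 = 2,052`, i.e. **53,764**.
5. **Evaluation.** Stratified 10-fold cross-validation with per-fold
   refitting of PCA and SWLDA (no leakage), confusion matrices as
   row-normalized recognition-rate tables, macro and support-weighted
   average rates, and per-class one-vs-rest sensitivity/specificity.
   Plug-in adapters allow baselines (majority, k-NN, random forest) to be
   run under the identical protocol.

A synthetic phantom generator (`synthSpec()` / `generateDataset()`) stands
in for the MRI collections: smooth elliptical "anatomy" plus class-specific
combinations of a few unit-norm low-frequency spatial modes plus i.i.d.
pixel noise, so the class signal provably lives in a low-dimensional
subspace of pixel space — exactly the regime the PCA + SWLDA front end
assumes. Every stage is exercisable without downloading any external data.

## Worked example

```r
library(swldanet)

spec <- synthSpec(imageHeight = 32, imageWidth = 32,
                  classNames = c("ND", "VMD", "MID", "MD"),
                  nPerClass = c(80, 56, 24, 8),   # imbalanced, like real data
                  effectSize = 1, noiseSd = 0.1, nSignalModes = 4, seed = 7)
phantom <- generateDataset(spec)
phantom
#> LabeledImageSet: 168 image(s) of 32 x 32 pixels
#> classes: ND (80), VMD (56), MID (24), MD (8)

report <- crossValidate(phantom, compactPipelineControl(seed = 7))
report
#> Recognition rates (%)
#>         ND   VMD MID   MD
#> ND  100.00  0.00   0  0.0
#> VMD   3.57 96.43   0  0.0
#> MID   0.00  0.00 100  0.0
#> MD   87.50  0.00   0 12.5
#> Average (macro): 77.23
#> Average (weighted): 94.64
```

The rows are the true classes; each row shows where those images were
routed, in percent. The three well-populated classes are recognized almost
perfectly, while the 8-image minority class mostly collapses into the
majority class — the macro average (unweighted mean of the diagonal, 77.23)
exposes this, whereas the support-weighted average (94.64, equal to overall
accuracy) hides it. On the balanced high-signal preset
(`highSignalSpec()`, 4 × 200 images) the same pipeline reaches a macro
average above 99%, and at `effectSize = 0` it sits at the 25% chance level.

The feature-selection stage can be inspected directly:

```r
X  <- flattenImages(filterDataset(phantom, 3))
em <- fitEigenModel(X, k = 40)
sel <- runStepwise(projectEigen(em, X), classLabels(phantom))
sel
#> SelectionResult: 28 feature(s) selected, terminated: no-candidate
selectionTrace(sel)        # per-step enter/remove partial F and p-values
countParameters(100, 512, 4)
#> [1] 53764
```

## Command line

```sh
Rscript inst/scripts/swldanet-cli synth --height 32 --width 32 \
    --classes a,b,c,d --per-class 50,50,50,50 --seed 1 --out data/
Rscript inst/scripts/swldanet-cli crossval --manifest data/manifest.csv \
    --height 32 --width 32 --pca-k 40 --hidden 64 --epochs 40 --out run/
```

Subcommands: `synth`, `preprocess`, `select`, `train`, `crossval`, `report`.

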