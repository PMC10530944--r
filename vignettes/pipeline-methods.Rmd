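---
title: "Methods: eigenimage features, stepwise discriminant selection, and a dense network classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenimage features, stepwise discriminant selection, and a dense network classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swldanet)
```

# The model

`swldanet` classifies same-size 2-D grayscale images into a small number of
classes through four fitted stages. The underlying assumption is that the
discriminative information is *global and low-dimensional*: class
differences are spread smoothly over the image and therefore concentrate in
the leading principal components of pixel space, where a modest linear or
mildly non-linear classifier can pick them up. This is the classic
eigenimage regime; it is appropriate for roughly registered medical slices
(all images show the same anatomy in the same pose) and inappropriate for
unregistered or translation-variant material.

## Mean filtering

Each pixel is replaced by the unweighted mean of its `size × size`
neighborhood (default 3, i.e. the 1/9 mask). The filter suppresses
uncorrelated pixel noise by a factor of `size` in standard deviation at the
cost of smearing edges; since the downstream features are global projections
this trade is almost free. Two conventions were open:

* **Border policy.** Replicate (edge-value) padding, so the output has the
  input's size and no artificial dark halo enters the covariance. Zero
  padding would create a spurious low-intensity frame that PCA would
  dutifully model.
* **Order of resize and filter.** The loader resizes first and the pipeline
  filters afterwards. Filtering before downscaling would act as a crude
  anti-alias filter; with bilinear resampling and smooth inputs the
  difference is marginal, but the order is a convention, not a derived
  fact, and is configurable by filtering a pre-sized dataset directly.

The implementation sums shifted copies of the padded image, which is exact
(the suite checks agreement with a literal double-loop oracle at `1e-12`);
an FFT-based convolution would only be approximately equal.

## Eigenimage features

Flattened images are rows of `X` (n × D). The model stores the per-pixel
mean, the top *K* eigenvectors of the covariance with divisor `n − 1`, and
their eigenvalues, computed via a rank-reduced SVD of the centered data so
that the D × D covariance is never materialized (for 128 × 128 images
D = 16,384). Conventions:

* **Divisor.** `n − 1`. It scales eigenvalues only, never directions; fixing
  it makes the score-variance identity (`var(score_k) = λ_k` on training
  data) exact and testable.
* **Sign.** Each eigenvector is flipped so its largest-magnitude entry is
  positive. Eigenvectors are only defined up to sign; fixing it makes
  serialized models byte-comparable across platforms.
* **K.** Default 150 at full size. The reference configuration of this
  method quotes three inconsistent widths downstream of PCA (150 retained
  components, a 125-feature selection cap, and a 100-input network); all
  three are plain configuration knobs here, downstream stages always size
  themselves from what the upstream stage actually produced, and the
  defaults keep the quoted values (150 / 125 / the selected count).
* **No leakage.** Inside cross-validation the basis is refitted on each
  training fold. A `globalFit` switch reproduces the leakier protocol of
  fitting PCA and selection once on all data, for comparison only.

## Stepwise discriminant selection

Labels are dummy-coded (`G − 1` columns, last class dropped — the full
one-hot block has a singular residual scatter and is used only for the
discriminant-weight solve). With `E` the residual cross-product matrix of
the indicator regression, a candidate feature's conditional contribution is
Wilks' `Λ = det(E_full)/det(E_reduced)`, converted to the exact single-df
partial F

`F = ((1 − Λ)/Λ) · (ν_E − m + 1)/m`, `df = (m, ν_E − m + 1)`, `m = G − 1`,

where `ν_E` is the residual degrees of freedom of the larger model. For
`G = 2` this is algebraically the squared partial *t* of the candidate's
coefficient — the classical two-class SWLDA criterion — and the test suite
pins that reduction at `1e-8` against an independent least-squares oracle,
plus the multi-class case against `anova.mlm(test = "Wilks")`.

The selection loop alternates forward entry (admit the candidate with the
smallest p-value if `p < alphaEnter`) and backward elimination (drop the
selected feature with the largest p-value if `p > alphaRemove`), with a
backward pass after every admission rather than only at convergence.
Parameters:

* `alphaEnter = 0.35`, `alphaRemove = 0.40` — the method's stated execution
  thresholds. (A stricter 0.15/0.2 pair is sometimes quoted for the initial
  model; it is available by passing those values to `stepwiseControl()`.)
  Note these are *liberal* thresholds: under a pure-noise null the smallest
  of many candidate p-values is usually below 0.35, so the procedure keeps
  admitting features until the cap or the degrees of freedom bind. That is
  faithful to the reference configuration (125 of 150 components retained)
  rather than a parsimony device.
* `maxFeatures = 125` — the selection cap; termination reason
  `"cap-reached"`.
* The constraint `alphaEnter ≤ alphaRemove` prevents enter/remove cycling;
  a `maxIterations` guard backstops pathological cases and its trip is
  surfaced as a warning plus termination reason `"iteration-guard"`, never
  silently.
* **Tie-breaks.** Equal p-values resolve to the lower feature id, making
  the trace deterministic and replayable.
* **Degenerate inputs.** A candidate (numerically) collinear with the
  selected set raises an error naming the feature in the single-candidate
  API and is skipped as ineligible inside the vectorized scan; a
  non-positive residual-scatter determinant aborts the scan. If no feature
  clears the entry threshold at all, cross-validation falls back to the
  leading principal component so the classifier still has an input.

The partial F is scale-free, so selection is invariant to per-feature
rescaling (tested by multiplying a column by 1000).

## Dense network

One hidden layer of 512 ReLU units with inverted dropout 0.5, softmax
output, categorical cross-entropy, Adam with learning rate 0.001, batch 32,
100 epochs, stratified validation split 0.25, no early stopping. Parameter
count: `input·hidden + hidden + hidden·output + output` (53,764 at
100/512/4). Unstated details resolved conventionally:

* Adam moments `β₁ = 0.9`, `β₂ = 0.999`, `ε = 1e-8`, recorded in the
  serialized control list.
* Weights initialized uniform `± sqrt(6 / fanIn)`, biases zero, from the
  control's seed; training is bit-reproducible on one platform.
* No class weighting: the reference protocol mentions none, and the
  imbalanced worked example in the README shows the consequence (minority
  class collapse) on purpose.

The network is implemented directly over base matrix algebra: at ~54k
parameters a deep-learning framework would add dependencies without
capability, and full control of the random stream keeps every test exact.

## Evaluation

`makeFolds()` shuffles within class (seeded) and deals round-robin with a
rotating offset, so per-fold class counts deviate from proportionality by at
most one and any class with ≥ 2 members reaches every training fold.
`summarizeConfusion()` reports the row-normalized percentage matrix, the
**macro average** (unweighted mean of diagonal recognition rates) and the
**weighted average** (support-weighted, algebraically equal to overall
accuracy). Published tables in this area sometimes label the unweighted
diagonal mean a "weighted average"; both are always computed here so the
naming cannot mislead. Display rounding is half-even at 2 decimals and
applies only to rendering; raw doubles are kept. A `percent = TRUE` path
summarizes an already-normalized rate table (e.g. a published one) whose
integer counts are unrecoverable; count-based per-class metrics are then
omitted.

# The phantom generator

`generateDataset()` emulates what matters to this pipeline: a shared smooth
elliptical base pattern ("anatomy"), a class-specific linear combination of
`nSignalModes` smooth unit-norm cosine-product modes scaled by
`effectSize`, and i.i.d. Gaussian pixel noise of sd `noiseSd`, clipped to
[0, 1]. Because the modes have unit L2 norm over the pixel grid, class
separation along a mode direction is `O(effectSize)` while noise contributes
standard deviation `noiseSd` along *every* direction — the two knobs are
directly comparable on the feature scale, and `effectSize = 0` removes all
class information by construction. The default spec mirrors a 10×
scaled-down version of the heavily imbalanced four-class MRI collection
(320/224/90/8), which exercises stratification edge cases cheaply.

What the phantoms deliberately do **not** model: anatomical texture,
registration error, intensity bias fields, scanner variation, or any
label-noise process. Passing the synthetic acceptance battery therefore
shows the pipeline is implemented correctly and behaves as designed in its
assumed regime; it says nothing about accuracy on real MRI, which depends on
how well real class differences concentrate in leading principal components.
The real-data noise and intensity model is unknown, so the phantom
parameters are conventions, not estimates.

Randomness discipline: the phantom structure (modes, class coefficients)
and the pixel noise are drawn from separate sub-streams derived from the
spec seed, so `synthSignalBasis()` can reproduce the structure without
touching the noise stream, and identical specs are bit-identical. Folds,
network initialization and dropout likewise derive from one root seed via
`deriveSeed()`.

# Study sizes used by the packaged runs

The calibrated presets keep complete runs at desk scale while leaving every
stage intact: `highSignalSpec()` uses 4 × 200 images at 32 × 32 with
`effectSize 1`, `noiseSd 0.1` (signal-to-noise 10 along mode directions —
comfortably separable by construction), and `noSignalSpec()` uses 4 × 100
with `effectSize 0`. `compactPipelineControl()` pairs them with 40
principal components, default stepwise thresholds, a 64-unit network for 40
epochs, and 10-fold evaluation. `scripts/acceptance.R` runs exactly these,
plus the parameter-count arithmetic and the published-table macro averages,
and writes all values as JSON.

# Known limitations

* Linear front end: class structure orthogonal to the leading principal
  components (fine texture, local lesions) is invisible to the pipeline.
* The liberal entry threshold makes selection behave more like ranked
  truncation than sparse selection when many candidates are available.
* No calibration of predicted probabilities is attempted; dropout plus
  fixed epochs can leave the softmax over- or under-confident.
* Minority classes receive no reweighting; with supports as skewed as
  320:8, per-class recall of the smallest class can collapse while overall
  accuracy stays high — report the macro average.
* The loader assumes images are roughly registered and aspect-compatible
  with the target size; it resizes without letterboxing.
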