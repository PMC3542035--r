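---
title: "Quantitative thyroid ultrasound texture analysis with thyrotex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative thyroid ultrasound texture analysis with thyrotex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrotex)
```

## The problem

Chronic autoimmune (Hashimoto) thyroiditis changes how thyroid parenchyma
looks on B-mode ultrasound: inflamed tissue is *hypoechogenic* (darker) and
more *heterogeneous* than healthy gland. Sonographers judge this visually;
`thyrotex` implements a quantitative pipeline that turns a rectangular
region of interest (ROI) marked inside the thyroid lobe into three texture
features, classifies the subject with Gaussian discriminant analysis, and —
crucially — measures how sensitive both the features and the diagnosis are
to how precisely the ROI was placed. That robustness protocol is the heart
of the package: an algorithm whose output swings wildly when the ROI moves
by a few pixels is not a usable measurement instrument, however good its
nominal accuracy.

## Preprocessing

Frames are 8-bit grayscale. Every frame is prefiltered with a 3×3 median
filter (edge replication at the borders, so the extent is preserved) before
the ROI is cropped; filtering the full frame rather than the crop means ROI
border pixels see their true neighborhood. ROIs are 1-based, inclusive
rectangles and may not be smaller than 10×10 px — the quadtree feature is
undefined below that.

## The three features

For an ROI image $L_s$ of $M_s \times N_s$ pixels:

**Smoothness** $w^{(1)} = 1 - \frac{1}{1 + \sigma^2}$, where $\sigma$ is
the *population* standard deviation of the gray levels divided by 255.
A flat region scores 0 and the score grows toward 1 with texture variance.
Normalizing by 255 puts typical thyroid speckle at $w^{(1)} \approx
10^{-3}$–$10^{-2}$. (The unnormalized 8-bit standard deviation would make
these values impossible; the definition printed as a sum of raw deviations
is identically zero and is read as a standard deviation, which is what its
symbol and surrounding text describe.)

**Noise-thresholded minimum brightness** $w^{(2)}$: build the 256-bin
histogram, find the modal count, discard every gray level whose count is
not *strictly* greater than 20% of the modal count, and return the lowest
surviving gray level. The modal bin always survives, so the feature is
always defined. It is a robust stand-in for "the darkest tissue present",
insensitive to isolated dark noise pixels. We return the surviving *gray
level*, not its count — that is what a minimum brightness is, and what the
feature's reported magnitudes (tens of gray levels) require.

**Quadtree 8×8 fraction** $w^{(3)}$: pad the ROI by edge replication to the
smallest power-of-two square $P \times P$, then recursively split any block
whose gray-level range (max − min) exceeds 10% of full scale (25.5 levels),
stopping at 1×1. $w^{(3)} = 100 \cdot 64 n_8 / P^2$ is the percentage of
the padded square tiled by final 8×8 blocks. It peaks for textures whose
heterogeneity lives at the ~8 px scale, which is where thyroid speckle
granularity sits at typical imaging resolutions. Edge replication (rather
than zero padding) avoids fabricating a high-contrast seam that would force
spurious splits; using $P^2$ as the denominator keeps $w^{(3)} \le 100$
exactly. The two denominator choices differ only for non-power-of-two ROIs.

```{r features}
img <- generate_texture(default_class_params("patient"), c(96, 96), seed = 7)
roi <- roi_spec(24, 24, 50, 50)
extract_features(extract_roi(median_filter3(img), roi))
```

## Classification

Feature triples are classified healthy vs patient with five discriminant
variants: `linear` (pooled covariance), `diaglinear` (pooled, diagonal),
`quadratic` (per-class), `diagquadratic` (per-class, diagonal) and
`mahalanobis` (per-class covariances, nearest class mean by Mahalanobis
distance, ignoring priors and determinant terms). Choices the source
material leaves open, fixed here: covariances use the $n-1$ denominator;
priors are empirical class frequencies; a singular covariance receives a
ridge of $10^{-6}\cdot\mathrm{tr}(\Sigma)/3$ on the diagonal (falling back
to $10^{-6}$ itself when the trace is zero, so that degenerate
constant-feature fits remain defined); score ties resolve to *healthy*,
which is the conservative direction for a screening tool.

Subjects contribute four views (left/right lobe × transverse/longitudinal:
LO, RO, LD, RD), evaluated singly and pooled (LRO, RLD, RLOD — seven
groupings). Splitting into learning/validation/test thirds happens at the
*subject* level so all four views of a gland stay in one partition;
image-level splitting would leak. The validation third is deliberately
unused by the discriminant suite and reserved for the tree baseline's
pruning selection, mirroring how the original protocol describes its
groups without ever consuming the validation set.

## Robustness protocol

The expert's ROI is treated as the only correct one; perturbations emulate
placement error at diagnosis time.

* **Shift**: ±20 px in rows and columns (beyond that the window leaves the
  lobe and samples neighboring anatomy).
* **Resize**: ±20 px per axis, applied symmetrically about the ROI center
  (odd changes put the extra pixel bottom/right); absolute sizes 10×10 to
  90×90.
* **Rotation**: 0–180° about the ROI center, bilinear interpolation,
  resampling from the *host* frame so the corners of the rotated window
  contain real neighboring tissue rather than synthetic fill.

Feature surfaces report $100\,(w_{pert}-w_{base})/w_{base}$ per cell. A
base feature of exactly 0 (possible for $w^{(1)}$ and $w^{(3)}$ on
degenerate textures) makes the percentage undefined; it is reported as
`NaN`, never silently 0, and distinct from `NA` which marks cells whose
perturbed ROI is illegal. Classification surfaces train once on unperturbed
features and perturb only the test ROIs — measurement error happens at
diagnosis, not at training; `retrain = TRUE` gives the other reading.
Rotation is excluded from classification surfaces by default because its
effect on the metrics is negligible relative to shift and resize; pass a
`rotation_grid` explicitly to include it. The zero cell of every surface is
an *exact* fixed point, asserted without tolerance in the tests. Because
the features are undefined below 10×10, classification-surface cells whose
shrunken ROI falls below that limit are masked even though the protocol
itself tolerates ROIs down to 5×5.

## Baselines

**Method 1** classifies an ROI as diseased when its mean brightness falls
below a fraction of saturation, swept over nine thresholds from 13% in
steps of 2.9% (the step is a tenth of the observed 10–39% range of ROI
means; exact steps end at 36.2%, the quoted "36%" being rounded). The
inequality's direction — darker ⇒ diseased — follows from hypoechogenicity.
It needs no training, so the sweep is resubstitution accuracy on all data.

**Method 2** is a CART-style tree on the feature triple: exhaustive
single-feature threshold search minimizing Gini impurity, stopping at pure
nodes or fewer than 5 samples; weakest-link cost-complexity pruning gives
levels 0 (unpruned) upward; the level is selected by the 1-SE rule on
10-fold cross-validated error (smallest tree within one standard error of
the minimum).

## The synthetic cohort

No clinical images are distributable, so the package ships a seeded
generator: base echogenicity × unit-mean gamma multiplicative speckle
(shape $1/s^2$ for dispersion $s$ — the standard first-order B-mode
speckle approximation), plus randomly placed ±contrast disk patches
emulating focal heterogeneity, Gaussian-smoothed to mimic finite beam
resolution, clipped and half-up quantized to 0–255. Defaults were
calibrated **once**, to the published feature ranges only
($w^{(1)}\!\approx\!0.001$–$0.01$, $w^{(2)}\!\approx\!30$–$60$,
$w^{(3)}\!\approx\!15$–$35$) and never to any classifier metric:

| class | mean level | speckle | blobs /1000 px² | contrast | smooth σ |
|---|---|---|---|---|---|
| healthy | 72 | 0.40 | 0.5 | 22 | 0.8 |
| patient | 50 | 0.40 | 2.5 | 30 | 0.8 |

giving mean features ≈ (0.0010, 59, 31) and (0.0018, 41, 30). The patient
class is darker and more heterogeneous, as in disease. Frames are 128×128
with a centered 50×50 ROI (the expert ROI size reported clinically),
leaving the ≥20 px margin every protocol perturbation needs. Views are
drawn independently — no intra-subject correlation is modeled, matching a
protocol that treats views as separate images everywhere.

What the generator does **not** emulate: point-spread functions,
attenuation, time-gain compensation, organ boundaries, or intra-subject
correlation. A green test on this cohort certifies that the pipeline's
mechanics (features, classifiers, surfaces, bookkeeping) are correct and
that the advertised class contrast is recoverable; it says nothing about
clinical accuracy on real glands.

```{r cohort}
cohort <- generate_cohort(cohort_config(12, 12, seed = 1))
feats <- extract_cohort_features(cohort)
head(run_grouped_evaluation(feats, seed = 1), 3)
```

## Numerical conventions

* Half-up rounding (`floor(x + 0.5)`) everywhere a gray level is quantized;
  R's banker's rounding would make results depend on parity.
* 1-based, inclusive ROI coordinates (R convention; internal C++ converts).
* Bilinear samples at exact right angles land on pixel centers, so 0°/90°/
  180° rotations are exact up to at most ±1 quantization — tested as such.
* All randomness (cohort, splits, CV folds) flows from explicit integer
  seeds; library RNG state is saved and restored around every seeded
  operation, and per-view and per-stage seeds derive deterministically from
  the master seed.

## Known limitations

* No DICOM reader is available in this build; convert to PNG/PGM first.
* Features require ROIs ≥ 10×10, so classification surfaces mask cells the
  clinical protocol would still allow (5×5–9×9) — irrelevant at the default
  ROI sizes.
* The mahalanobis variant ignores priors by construction and is expected to
  trade specificity for sensitivity relative to the others.
* Published clinical accuracies are not reproducible here; nothing in the
  test suite or vignette asserts them.
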