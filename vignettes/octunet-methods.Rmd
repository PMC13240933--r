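---
title: "Methods: epidermal segmentation of OCT B-scans with a compact U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epidermal segmentation of OCT B-scans with a compact U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optical coherence tomography (OCT) resolves the layered structure of skin a
millimetre or two below the surface. In actinic keratosis (AK), the thickness
of the epidermis and the integrity of the dermal-epidermal junction (DEJ) are
the clinically relevant quantities, but tracing the epidermis by hand on
every B-scan is slow and observer-dependent — and hyperkeratosis, low DEJ
contrast and hair shadowing all make the boundary genuinely ambiguous in
places. `octunet` implements a deliberately small encoder–decoder
convolutional network that segments the epidermis pixel-wise from a single
grayscale B-scan, together with everything needed to train, tune and audit
it: a synthetic phantom generator with exact ground truth, a seven-metric
evaluation suite, per-column epidermal thickness (ET) with Pearson and
Bland–Altman agreement analysis, and a hyperparameter sweep with overfit
diagnosis.

Because clinical OCT datasets of AK are generally not redistributable, the
package is built to be fully exercisable on synthetic data: every stage of
the pipeline is tested end-to-end against phantoms whose epidermis mask is
known exactly, and the same code paths accept real PNG/TIFF B-scans and
masks when they are available.

## The network

The model is a U-Net with `encoder_depth` (default 2) encoder blocks, a
bottleneck, and a mirrored decoder. Each block applies two 3×3 convolutions
with rectified-linear activations; "same" zero padding keeps spatial size
unchanged inside a block, so the output raster always matches the input
raster. Encoder blocks end in 2×2 max pooling; decoder blocks begin with a
*learned* 2×2 stride-2 transposed convolution — a 2×2 upsampling filter
rather than the more common 3×3, which quarters the upsampling cost without
losing single-pixel localization — followed by concatenation with the
matching encoder output through a skip connection. A final 1×1 convolution
and sigmoid produce a per-pixel epidermis probability in [0, 1]. Input
dimensions must be divisible by `2^encoder_depth`; non-divisible sizes are
rejected with guidance rather than silently padded (the sweep module instead
reflection-pads and crops back, and records that it did so).

Channel widths double per level. The default `base_filters = 8` (8, 16
encoder; 32 bottleneck; ~29k parameters) was chosen once, on capacity and
hardware grounds: single-band segmentation of a layered tissue is a low
complexity task, width 8 trains to high validation accuracy on phantoms, and
the doubled width costs roughly four times the (memory-bandwidth-bound)
compute on a plain CPU without changing the attainable accuracy band on this
task. The width is a constructor argument, so any study can widen it.

Everything — the forward pass, backpropagation and the Adam optimizer — is
implemented in the package on top of base R matrix algebra. The 3×3
convolutions are evaluated as im2col + GEMM in strip-blocked compiled
kernels (`src/conv_kernels.cpp`): for a block of image columns the patch
matrix is built in a ~4 MB buffer, multiplied through BLAS, and written
back, so the full patch matrix is never materialized. This keeps the
working set near cache size, which matters more than arithmetic throughput
for these thin, memory-bound GEMM shapes. Backpropagation was verified
against central finite differences to ~1e-10 (the test suite keeps a
smaller version of that check). One caveat worth recording: with
zero-initialized biases, pre-activations can sit *exactly* on the ReLU
kink wherever an entire input patch is zero, and there the two-sided
numerical derivative legitimately disagrees with the (sub)gradient; the
gradient test therefore jitters biases off zero first.

## Training strategy

Training minimizes pixel-wise binary cross-entropy with Adam at learning
rate 0.001. The dataset splits 80/20 into train+validation/test — 60 items
give the 48/12 convention — with the validation set a further 20% fraction
of the non-test items; test items are never seen during training. The loop
applies early stopping on validation loss (default patience 10 epochs) and
reduce-on-plateau learning-rate adjustment (factor 0.5 after 5 stagnant
epochs), and returns the weights of the best-validation-loss epoch. The
loss function, validation fraction and both patience values are implementer
defaults — recorded in every run's provenance file — since reasonable
choices here are not unique. All randomness (split, shuffling,
initialization) is keyed to two explicit integer seeds, so runs are
bit-reproducible.

The logged "accuracy" is pixel accuracy of the 0.5-thresholded prediction.
Note that a lazy all-background predictor already scores ~0.9 on these
images (the band occupies ~10% of pixels), which is exactly why the
evaluation below leans on Dice/Jaccard rather than accuracy.

Overfit diagnosis follows the divergence signature visible in training
curves: flagged when the final validation loss exceeds the final training
loss by more than `gap_margin` (default 0.1) *and* the validation loss
slope over the last `trend_window` epochs (default 5, least squares on
epoch index) is positive while the training loss slope is not.

## Evaluation metrics

Seven metrics compare a predicted mask against ground truth: accuracy,
precision, recall, Jaccard index (IoU), Dice coefficient, mean absolute
error (MAE), and Hausdorff distance. The first five derive from the pixel
confusion counts; Dice and Jaccard obey the exact identity
$D = 2J/(1+J)$, and on binary masks accuracy equals $1 - \mathrm{MAE}$
exactly — both identities are asserted in the tests. MAE is computed from
the per-pixel formula $\frac{1}{N}\sum_i |y_i - \hat y_i|$ on binary masks
(a probability-map mode exists behind a flag); it is therefore a
dimensionless per-pixel rate even though it is conventionally quoted "in
pixels".

The Hausdorff distance is the max form — the larger of the two directed
maxima of minimum Euclidean distances between boundary pixel sets — with no
percentile variant. Boundaries use 4-adjacency with the image border
counting as background, so a band touching the edge still produces a closed
boundary; coordinates are 0-based (row, col) with row increasing into the
tissue. The implementation is chunk-vectorized but required to agree with
an O(|A|·|B|) brute force to 1e-9, which the test suite checks on 200
random mask pairs.

Division-by-zero conventions: precision with an empty prediction (and
recall with an empty truth) are undefined — reported as `NA` with a warning
and scored 0 in directory-level aggregates, so that averages are not
silently inflated; Dice/Jaccard between two empty masks are 1, because
agreement on emptiness is perfect agreement. An empty boundary makes the
Hausdorff distance an *error* that states which side was empty: an empty
prediction is a total segmentation failure, not a number.

Qualitative bands contextualize the numbers: overlap scores are acceptable
above 0.7, good above 0.8, excellent above 0.93; MAE below 1 and Hausdorff
below 25 px are good, with 1–1.5 and 25–70 px acceptable. Because whether a
published test-set metric is a mean over images or a pooled-pixel
computation is often ambiguous, `evaluate_mask_dirs()` emits both a
per-image `mean` row and a `pooled` row from summed confusion counts.

## Epidermal thickness and agreement

ET is computed per image column as the vertical span between the upper and
lower epidermal boundaries (last − first foreground row + 1). Columns with
no foreground are excluded from the mean rather than zero-filled — an
explicit, documented choice. Columns with multiple foreground runs (possible
in noisy predictions) are spanned by their outer envelope by default,
matching the upper/lower-boundary definition; a `strict` mode flags them
instead. The pixel→µm conversion is a required explicit input (default
5.5 µm/px, a typical axial figure for swept-source skin OCT) because
stored axial pitch varies by device and export settings; every µm output
carries the factor used.

Agreement between manual and automated ET uses Pearson correlation
(two-sided) and Bland–Altman analysis: bias is the mean of
(automated − manual), and the 95% limits of agreement are bias ± 1.96·SD
with the n−1 sample standard deviation — 1.96, not 2.0, to match the 95%
convention. Paired comparisons of metrics across B-scan positions (25%,
50%, 75% of a volume) use two-sided paired t-tests at α = 0.05, with honest
degeneracies: all-zero differences report p = 1, constant nonzero
differences are labelled degenerate rather than given a spurious p-value.

## The phantom generator

The generator emulates the geometry of a swept-source skin OCT B-scan
(native canvas 464×1356 px — a 6 mm lateral field at 4.4 µm fast-axis
sampling — with a 256×256 quick preset for fast experiments): a near-black
air gap, a bright entrance surface forming the top of the epidermis, a
mid-intensity epidermis band bounded below by a smooth DEJ, and a textured
dermis that decays exponentially with depth. Surfaces and DEJ are sums of a
few low-frequency sinusoids with seeded random phases — smooth,
band-limited boundaries. Speckle is multiplicative unit-mean gamma noise
parameterized by its contrast ratio (first-order speckle statistics; unit
mean leaves expected layer intensities unchanged). Optional pathology-like
features: a raised-cosine hyperkeratotic bump that locally thickens and
brightens the band, and Poisson-distributed vertical hair shadows that
*darken* (×0.15–0.35) a 3–10-column span below the surface — darkening
rather than zeroing, so no mask column becomes empty. Every phantom is a
deterministic function of its spec, including the seed, and its mask is by
construction a single contiguous vertical run per column whose length
equals the returned thickness profile exactly — the closure property the
thickness module is tested against.

Default geometry (quick preset: entrance near row 40, band 24 ± 7 px,
speckle contrast 0.35, ~1 shadow per image, 30% hyperkeratosis incidence)
was set once to resemble moderate AK morphology at that scale and is not a
tuning surface. What the phantoms deliberately do **not** model: confocal
gating, refraction, PSF convolution, sensor noise floors, or any specific
clinical severity grade. Passing the synthetic end-to-end test therefore
demonstrates that the pipeline is *correctly wired and trainable* — not
that it meets any particular accuracy on clinical data.

## The hyperparameter sweep

The sweep enumerates image size × batch size × epochs (defaults: 256×256,
512×512, 1024×1024, 464×1356; 2/4/8/16; 50/100/150 — a 48-cell grid,
size-major order) or an explicit configuration list. All configurations
share one split, train from identical seeds, and are evaluated on the same
test partition; each row records the seven metrics, final losses, the
overfit flag, parameter count and wall time (logged but never used for
selection, being hardware-dependent). A failed configuration is recorded
as failed and the sweep continues. Selection defaults to maximum Dice with
ties broken by higher Jaccard, then lower Hausdorff, then fewer parameters;
minimum validation loss and minimum MAE are selectable alternatives.

## Problem sizes and numerical choices

The package's own reference experiment — run by `scripts/acceptance.R` and
mirrored in the test suite — uses 60 quick-preset phantoms (48 train+val /
12 test), the 256×256 / batch 2 / ≤50 epoch configuration, and
`base_filters = 8`; on one desktop-class CPU core this trains in roughly 12
minutes. Unit tests use 32×32 phantoms and 2–4 filter models so the
whole suite stays fast.

Numerical details worth knowing: binary cross-entropy is evaluated through
a stable softplus; `binarize()` uses the ≥ threshold convention; max-pool
ties resolve deterministically to the first window element; weight
initialization is He-style normal (variance 2/fan-in) with zero biases;
Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8. Model checkpoints are single RDS
files with a sidecar JSON describing the architecture, so they are
self-describing. Provenance records are timestamp-free so identical runs
write identical bytes.

## Known limitations

* The phantoms are statistically far simpler than clinical AK B-scans; the
  end-to-end surrogate bounds implementation correctness, not clinical
  performance.
* Training is CPU-only and single-threaded beyond BLAS; large (≥512²)
  training runs are slow by design honesty rather than engineering effort.
* No data augmentation is implemented, and only a single random split is
  used by default (repeated-split experiments are possible by varying
  `split_seed`).
* 3D/volumetric segmentation, percentile Hausdorff variants and average
  surface distances are out of scope.
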