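# octunet

Automated epidermal segmentation in optical coherence tomography (OCT)
B-scans of skin, for researchers quantifying actinic keratosis (AK) and
related keratinocyte pathology. Manual delineation of the epidermis and the
dermal-epidermal junction (DEJ) is slow and observer-dependent, and
AK-specific features — hyperkeratosis, low DEJ contrast, hair shadowing —
make it genuinely hard. `octunet` provides a compact, CPU-trainable
U-Net for pixel-wise epidermis segmentation plus the complete surrounding
pipeline: synthetic speckle phantoms with exact ground truth, training with
early stopping and learning-rate scheduling, a seven-metric evaluation
suite, epidermal-thickness agreement analysis, and a hyperparameter sweep.

## The model

A depth-2 encoder–decoder U-Net: each block is two 3×3 "same"-padded
convolutions with ReLU; encoder blocks end in 2×2 max pooling; decoder
blocks start with a learned 2×2 stride-2 transposed convolution and
concatenate the matching encoder features through a skip connection; a
final 1×1 convolution with a sigmoid yields a probability map the same
size as the input. Channel widths double per level (default 8, 16;
bottleneck 32; ≈29k parameters). Training minimizes pixel-wise binary
cross-entropy with Adam (lr 0.001) on an 80/20 train+validation/test split.

Predicted masks are scored against ground truth with

- accuracy (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN),
- Jaccard J = TP/(TP+FP+FN), Dice D = 2TP/(2TP+FP+FN) (so D = 2J/(1+J)),
- MAE = Σ|yᵢ−ŷᵢ|/N,
- Hausdorff distance d_H = max( max_{a∈L_A} min_{b∈L_B} d(a,b),
  max_{b∈L_B} min_{a∈L_A} d(a,b) ) over boundary pixel sets,

and epidermal thickness (per-column vertical span of the mask, converted to
µm by the axial pixel pitch) is compared manual-vs-automated by Pearson
correlation and Bland–Altman bias ± 1.96·SD limits of agreement.

The network, backpropagation and optimizer are implemented in the package
(R + strip-blocked C++ im2col/GEMM kernels); no external deep-learning
framework is required.

## Worked example

Phantoms stand in for clinical scans (which are not redistributable), so
the whole pipeline runs out of the box:

```r
library(octunet)

# 15 synthetic 256x256 B-scans with known epidermis masks
ds <- lapply(1:15, function(i) {
  p <- generate_phantom(phantom_preset("quick", seed = 100 + i))
  list(image = p$image, mask = p$mask)
})
names(ds) <- sprintf("scan%02d", 1:15)

split <- split_dataset(names(ds), seed = 1)   # 10 train / 2 val / 3 test
cfg   <- train_config(image_size = c(256, 256), batch_size = 2, epochs = 25)
model <- build_unet(unet_config(256, 256, base_filters = 8), seed = 2)
run   <- train_unet(model, ds, split, cfg, verbose = TRUE)

id   <- split$test[1]
pred <- binarize(unet_predict(run$model, ds[[id]]$image))
evaluate_masks(pred, ds[[id]]$mask)
```

```
  accuracy     0.9827  [excellent]
  precision    0.8914  [good]
  recall       0.9279  [good]
  jaccard      0.8337  [good]
  dice         0.9093  [good]
  mae          0.0173  [good]
  hausdorff   37.3363  [acceptable]
```

Dice/Jaccard say the predicted band overlaps most of the true epidermis;
MAE is the per-pixel error rate (accuracy = 1 − MAE on binary masks); the
Hausdorff value means the worst boundary excursion is ~37 px. Thickness
agreement across the (three) test scans:

```r
pitch <- 5.5  # axial um per pixel
man <- sapply(split$test, function(i) thickness_profile(ds[[i]]$mask, pitch)$mean_um)
aut <- sapply(split$test, function(i)
  thickness_profile(binarize(unet_predict(run$model, ds[[i]]$image)), pitch)$mean_um)
compare_thickness(man, aut)
```

```
agreement_stats (n = 3): bias 22.831 um, 95% LoA [8.964, 36.698] um
  Pearson r = 0.423 (p = 0.722)
```

With only ten training images the model still over-segments noticeably
(the positive thickness bias); the reference experiment below, at the full
60-phantom scale, reaches Dice ≈ 0.96, a mean Hausdorff ≈ 24 px and an ET
bias of ≈ +7 µm (about one pixel of over-segmentation).

A thin command-line layer wraps the same functions
(`inst/cli/octunet generate|train|evaluate|thickness|agree|sweep|select|config`),
and `run_sweep()` / `select_best()` reproduce the image-size × batch ×
epochs study with a shared split and Dice-based model selection.

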