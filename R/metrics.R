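#' Threshold a probability map into a binary epidermis mask
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' `threshold`.
#'
#' @param map Numeric matrix of probabilities in \[0, 1\].
#' @param threshold Scalar in (0, 1); default 0.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(map, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  out <- matrix(0L, nrow(map), ncol(map))
  out[map >= threshold] <- 1L
  out
}

check_binary_mask <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  invisible(m)
}

check_same_shape <- function(a, b, caller) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s: shape mismatch (%s vs %s)", caller,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

#' Pixel-level confusion counts between predicted and true masks
#'
#' @param pred,truth Binary 0/1 matrices of equal shape.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn` (summing to the number of pixels compared).
#' @export
confusion_counts <- function(pred, truth) {
  check_same_shape(pred, truth, "confusion_counts")
  check_binary_mask(pred, "pred"); check_binary_mask(truth, "truth")
  p <- pred > 0; t <- truth > 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Computes accuracy, precision, recall, Jaccard index (IoU) and Dice
#' coefficient. Conventions for undefined ratios: precision with
#' `tp + fp = 0` (empty prediction) and recall with `tp + fn = 0` (empty
#' truth) are returned as `NA` with a warning; Dice and Jaccard when both
#' masks are empty (`tp + fp + fn = 0`) are 1, since agreement on emptiness
#' is perfect agreement.
#'
#' @param cc A [confusion_counts()] object (or list with tp/fp/fn/tn).
#' @return Named list: `accuracy`, `precision`, `recall`, `jaccard`, `dice`.
#' @export
overlap_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  n <- tp + fp + fn + tn
  if (n == 0) stop("overlap_metrics: no pixels compared (N = 0)", call. = FALSE)
  precision <- if (tp + fp == 0) {
    warning("precision undefined: prediction has no foreground pixels")
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("recall undefined: ground truth has no foreground pixels")
    NA_real_
  } else tp / (tp + fn)
  denom <- tp + fp + fn
  jaccard <- if (denom == 0) 1 else tp / denom
  dice <- if (denom == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       jaccard = jaccard, dice = dice)
}

#' Mean absolute error between two masks (or maps)
#'
#' The per-pixel mean of `|y - y_hat|`. On binary masks this equals
#' `(fp + fn) / N`, the complement of accuracy.
#'
#' @param pred,truth Matrices of equal shape; binary unless
#'   `mode = "probability"`.
#' @param mode `"binary"` (default, validates 0/1 inputs) or
#'   `"probability"` (accepts values in \[0, 1\]).
#' @return Scalar error in \[0, 1\] for binary/probability inputs.
#' @export
mask_mae <- function(pred, truth, mode = c("binary", "probability")) {
  mode <- match.arg(mode)
  check_same_shape(pred, truth, "mask_mae")
  if (mode == "binary") {
    check_binary_mask(pred, "pred"); check_binary_mask(truth, "truth")
  }
  mean(abs(as.numeric(pred) - as.numeric(truth)))
}

#' Extract the boundary pixel set of a binary mask
#'
#' A boundary pixel is a foreground pixel 4-adjacent to at least one
#' background pixel or lying on the image border (the border counts as
#' background, so a band touching the edge still yields a closed boundary).
#'
#' @param mask Binary 0/1 matrix.
#' @return Two-column integer matrix of 0-based `(row, col)` coordinates
#'   (row increases with depth), ordered column-major; zero rows for an
#'   empty mask.
#' @export
extract_boundary <- function(mask) {
  check_binary_mask(mask, "mask")
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask > 0
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- fg
  nb_all <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  bnd <- fg & !nb_all
  idx <- which(bnd)
  cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
}

directed_hausdorff <- function(a, b, chunk = 1024L) {
  worst <- 0
  i <- 1L
  nb1 <- b[, 1L]; nb2 <- b[, 2L]
  while (i <= nrow(a)) {
    j <- min(nrow(a), i + chunk - 1L)
    dr <- outer(a[i:j, 1L], nb1, "-")
    dc <- outer(a[i:j, 2L], nb2, "-")
    dmin <- sqrt(apply(dr * dr + dc * dc, 1L, min))
    worst <- max(worst, max(dmin))
    i <- j + 1L
  }
  worst
}

#' Hausdorff distance between two boundary point sets
#'
#' The symmetric Hausdorff distance: the larger of the two directed maxima
#' of minimum Euclidean point-to-set distances, in pixel units.
#'
#' @param a,b Two-column `(row, col)` coordinate matrices (e.g. from
#'   [extract_boundary()]) or binary masks, which are converted via
#'   [extract_boundary()]. By convention `a` is the prediction and `b` the
#'   ground truth; an empty set raises an error saying which side is empty
#'   (an empty prediction signals total segmentation failure).
#' @return Scalar distance in pixels; 0 iff the sets are equal.
#' @export
hausdorff_distance <- function(a, b) {
  if (is.matrix(a) && !(ncol(a) == 2L && !is.null(colnames(a)) &&
                        all(colnames(a) == c("row", "col"))) && all(a %in% c(0, 1)))
    a <- extract_boundary(a)
  if (is.matrix(b) && !(ncol(b) == 2L && !is.null(colnames(b)) &&
                        all(colnames(b) == c("row", "col"))) && all(b %in% c(0, 1)))
    b <- extract_boundary(b)
  if (nrow(a) == 0L)
    stop("hausdorff_distance: empty prediction boundary (no foreground predicted)",
         call. = FALSE)
  if (nrow(b) == 0L)
    stop("hausdorff_distance: empty truth boundary (ground truth has no foreground)",
         call. = FALSE)
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' Qualitative performance bands
#'
#' Overlap scores (accuracy, precision, recall, Jaccard, Dice) are banded as
#' excellent (> 0.93), good (> 0.8), acceptable (> 0.7), else poor. MAE is
#' good below 1, acceptable up to 1.5; Hausdorff distance is good below 25
#' px, acceptable up to 70 px.
#'
#' @param value Metric value.
#' @param metric One of `"overlap"`, `"mae"`, `"hausdorff"`.
#' @return Character band label.
#' @export
performance_band <- function(value, metric = c("overlap", "mae", "hausdorff")) {
  metric <- match.arg(metric)
  if (is.na(value)) return(NA_character_)
  switch(metric,
    overlap = if (value > 0.93) "excellent" else if (value > 0.8) "good"
              else if (value > 0.7) "acceptable" else "poor",
    mae = if (value < 1) "good" else if (value <= 1.5) "acceptable" else "poor",
    hausdorff = if (value < 25) "good" else if (value <= 70) "acceptable" else "poor"
  )
}

#' Full seven-metric evaluation of a predicted mask against ground truth
#'
#' Computes accuracy, precision, recall, Jaccard, Dice, mean absolute error
#' and Hausdorff distance, each with its qualitative band.
#'
#' @param pred,truth Binary 0/1 matrices of equal shape.
#' @return An object of class `metric_report`: list with the seven metric
#'   values, a `bands` character vector, and the underlying
#'   `confusion_counts`.
#' @export
evaluate_masks <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  om <- overlap_metrics(cc)
  mae <- mask_mae(pred, truth)
  hd <- hausdorff_distance(extract_boundary(pred), extract_boundary(truth))
  vals <- c(accuracy = om$accuracy, precision = om$precision,
            recall = om$recall, jaccard = om$jaccard, dice = om$dice,
            mae = mae, hausdorff = hd)
  bands <- c(vapply(vals[1:5], performance_band, character(1), metric = "overlap"),
             mae = performance_band(mae, "mae"),
             hausdorff = performance_band(hd, "hausdorff"))
  structure(c(as.list(vals), list(bands = bands, counts = cc)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (m in c("accuracy", "precision", "recall", "jaccard", "dice",
              "mae", "hausdorff")) {
    cat(sprintf("  %-10s %8.4f  [%s]\n", m, x[[m]], x$bands[[m]]))
  }
  invisible(x)
}

#' Evaluate directories of predicted vs ground-truth masks
#'
#' Mask PNGs are matched by sorted file name. Emits one row per image plus a
#' `mean` row (undefined per-image metrics count as 0 in the mean, after a
#' warning at computation time) and a `pooled` row computed from summed
#' confusion counts over all pixels of all images.
#'
#' @param pred_dir,truth_dir Directories of mask PNG files, equal counts.
#' @return `data.frame` with columns `image`, `accuracy`, `precision`,
#'   `recall`, `jaccard`, `dice`, `mae`, `hausdorff`.
#' @export
evaluate_mask_dirs <- function(pred_dir, truth_dir) {
  pf <- sort(list.files(pred_dir, pattern = "\\.png$", full.names = TRUE))
  tf <- sort(list.files(truth_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(pf) == 0L) stop("evaluate_mask_dirs: no PNG masks in pred dir", call. = FALSE)
  if (length(pf) != length(tf))
    stop("evaluate_mask_dirs: differing numbers of prediction and truth masks",
         call. = FALSE)
  rows <- vector("list", length(pf))
  pooled <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(pf)) {
    pred <- read_mask_png(pf[i]); truth <- read_mask_png(tf[i])
    rep_i <- evaluate_masks(pred, truth)
    pooled <- Map(`+`, pooled, rep_i$counts[c("tp", "fp", "fn", "tn")])
    rows[[i]] <- data.frame(image = basename(pf[i]),
                            accuracy = rep_i$accuracy, precision = rep_i$precision,
                            recall = rep_i$recall, jaccard = rep_i$jaccard,
                            dice = rep_i$dice, mae = rep_i$mae,
                            hausdorff = rep_i$hausdorff)
  }
  tab <- do.call(rbind, rows)
  num <- tab[, -1L, drop = FALSE]
  num[is.na(num)] <- 0
  mean_row <- data.frame(image = "mean", t(colMeans(num)))
  pm <- overlap_metrics(structure(pooled, class = "confusion_counts"))
  n_pool <- sum(unlist(pooled))
  pooled_row <- data.frame(image = "pooled", accuracy = pm$accuracy,
                           precision = pm$precision, recall = pm$recall,
                           jaccard = pm$jaccard, dice = pm$dice,
                           mae = (pooled$fp + pooled$fn) / n_pool,
                           hausdorff = NA_real_)
  rbind(tab, mean_row, pooled_row)
}
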