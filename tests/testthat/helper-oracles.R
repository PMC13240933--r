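# Independent brute-force oracles for the segmentation metrics. These are
# deliberately naive (explicit loops over pixels and point pairs) so they
# share no code path with the package implementations they check.

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] > 0; t <- truth[i, j] > 0
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_overlap <- function(cc) {
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  list(accuracy = (cc$tp + cc$tn) / n,
       precision = cc$tp / (cc$tp + cc$fp),
       recall = cc$tp / (cc$tp + cc$fn),
       jaccard = cc$tp / (cc$tp + cc$fp + cc$fn),
       dice = 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn))
}

oracle_mae <- function(pred, truth) {
  s <- 0
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred)))
      s <- s + abs(pred[i, j] - truth[i, j])
  s / length(pred)
}

oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (mask[i, j] == 0) next
      on_border <- i == 1 || i == H || j == 1 || j == W
      nb_bg <- (i > 1 && mask[i - 1, j] == 0) || (i < H && mask[i + 1, j] == 0) ||
        (j > 1 && mask[i, j - 1] == 0) || (j < W && mask[i, j + 1] == 0)
      if (on_border || nb_bg) pts <- rbind(pts, c(i - 1L, j - 1L))
    }
  }
  if (is.null(pts)) matrix(integer(0), 0, 2) else pts
}

oracle_hausdorff <- function(a, b) {
  dab <- 0
  for (i in seq_len(nrow(a))) {
    dmin <- Inf
    for (j in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dab <- max(dab, dmin)
  }
  dba <- 0
  for (j in seq_len(nrow(b))) {
    dmin <- Inf
    for (i in seq_len(nrow(a)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dba <- max(dba, dmin)
  }
  max(dab, dba)
}

random_mask <- function(h, w, p) matrix(rbinom(h * w, 1L, p), h, w)
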