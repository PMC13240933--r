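test_that("binarize follows the >= threshold convention", {
  u <- matrix(0.5, 4, 4)
  expect_true(all(binarize(u, 0.5) == 1L))
  expect_true(all(binarize(matrix(0, 4, 4), 0.5) == 0L))
  truth <- random_mask(8, 8, 0.4)
  for (thr in c(0.1, 0.5, 0.9))
    expect_identical(binarize(matrix(as.numeric(truth), 8, 8), thr), truth)
})

test_that("confusion counts match the brute-force tally", {
  truth <- matrix(0L, 4, 4); truth[2:3, 2:3] <- 1L   # k = 4 of N = 16
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 4L, fp = 0L, fn = 0L, tn = 12L))
  all_fg <- matrix(1L, 4, 4)
  cc2 <- confusion_counts(all_fg, truth)
  expect_equal(unclass(cc2)[c("tp", "fp", "fn", "tn")],
               list(tp = 4L, fp = 12L, fn = 0L, tn = 0L))
  set.seed(42)
  for (rep in 1:10) {
    a <- random_mask(8, 8, runif(1, 0.2, 0.8))
    b <- random_mask(8, 8, runif(1, 0.2, 0.8))
    expect_equal(unclass(confusion_counts(a, b))[c("tp", "fp", "fn", "tn")],
                 oracle_confusion(a, b))
    # symmetry: swapping pred/truth swaps fp and fn
    cab <- confusion_counts(a, b); cba <- confusion_counts(b, a)
    expect_identical(cab$tp, cba$tp)
    expect_identical(cab$fp, cba$fn)
  }
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shape mismatch")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0L, 2, 2)), "binary")
})

test_that("overlap metrics give textbook values and handle edge conventions", {
  m <- overlap_metrics(structure(list(tp = 6, fp = 2, fn = 2, tn = 6),
                                 class = "confusion_counts"))
  expect_equal(m$dice, 0.75)
  expect_equal(m$jaccard, 0.6)
  expect_equal(2 * m$jaccard / (1 + m$jaccard), m$dice)
  perfect <- overlap_metrics(structure(list(tp = 5, fp = 0, fn = 0, tn = 11),
                                       class = "confusion_counts"))
  expect_true(all(unlist(perfect) == 1))
  disjoint <- overlap_metrics(structure(list(tp = 0, fp = 3, fn = 4, tn = 9),
                                        class = "confusion_counts"))
  expect_equal(disjoint$dice, 0)
  expect_equal(disjoint$jaccard, 0)
  # agreement on emptiness is perfect agreement (both ratios warn as undefined)
  empty <- suppressWarnings(
    overlap_metrics(structure(list(tp = 0, fp = 0, fn = 0, tn = 16),
                              class = "confusion_counts")))
  expect_equal(empty$dice, 1)
  expect_equal(empty$jaccard, 1)
  expect_warning(pr <- overlap_metrics(structure(
    list(tp = 0, fp = 0, fn = 3, tn = 13), class = "confusion_counts")),
    "precision undefined")
  expect_true(is.na(pr$precision))
  expect_error(overlap_metrics(structure(list(tp = 0, fp = 0, fn = 0, tn = 0),
                                         class = "confusion_counts")), "N = 0")
})

test_that("the Dice-Jaccard identity holds on random confusion tables", {
  set.seed(7)
  for (rep in 1:50) {
    cc <- structure(as.list(c(tp = sample(0:50, 1), fp = sample(0:50, 1),
                              fn = sample(0:50, 1), tn = sample(1:50, 1))),
                    class = "confusion_counts")
    m <- overlap_metrics(cc)
    expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
    expect_gte(m$dice, m$jaccard)
  }
})

test_that("mask MAE equals the per-pixel mean difference and (fp+fn)/N", {
  a <- matrix(0L, 4, 4)
  expect_equal(mask_mae(a, a), 0)
  b <- a; b[1, 1] <- 1L; b[2, 2] <- 1L
  expect_equal(mask_mae(b, a), 2 / 16)
  set.seed(9)
  for (rep in 1:10) {
    p <- random_mask(8, 8, 0.5); t <- random_mask(8, 8, 0.5)
    cc <- confusion_counts(p, t)
    expect_equal(mask_mae(p, t), (cc$fp + cc$fn) / 64)
    expect_equal(mask_mae(p, t), oracle_mae(p, t))
    # on binary masks accuracy is exactly 1 - MAE
    expect_equal(overlap_metrics(cc)$accuracy, 1 - mask_mae(p, t))
  }
  expect_equal(mask_mae(matrix(0.25, 2, 2), matrix(0.75, 2, 2),
                        mode = "probability"), 0.5)
})

test_that("boundary extraction follows 4-adjacency with border-as-background", {
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_equal(extract_boundary(single),
               cbind(row = 2L, col = 2L))
  block <- matrix(0L, 8, 8); block[3:6, 3:6] <- 1L
  bnd <- extract_boundary(block)
  expect_equal(nrow(bnd), 12)        # perimeter ring of a 4x4 block
  expect_false(any(bnd[, 1] %in% 3:4 & bnd[, 2] %in% 3:4))  # interior excluded
  full <- matrix(1L, 6, 6)
  bf <- extract_boundary(full)
  expect_equal(nrow(bf), 20)         # border pixels only
  expect_true(all(bf[, 1] %in% c(0, 5) | bf[, 2] %in% c(0, 5)))
  expect_equal(nrow(extract_boundary(matrix(0L, 4, 4))), 0)
  set.seed(3)
  for (rep in 1:5) {
    m <- random_mask(7, 9, 0.5)
    got <- extract_boundary(m)
    want <- oracle_boundary(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("Hausdorff distance is exact, symmetric and error-distinguishing", {
  expect_equal(hausdorff_distance(cbind(row = 0, col = 0),
                                  cbind(row = 3, col = 4)), 5.0)
  set.seed(5)
  a <- cbind(row = sample(0:20, 6), col = sample(0:20, 6))
  expect_equal(hausdorff_distance(a, a), 0)
  expect_equal(hausdorff_distance(cbind(row = c(0, 0), col = c(0, 10)),
                                  cbind(row = 0, col = 0)), 10.0)
  for (rep in 1:10) {
    a <- cbind(row = sample(0:15, 5), col = sample(0:15, 5))
    b <- cbind(row = sample(0:15, 4), col = sample(0:15, 4))
    expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b))
    expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
    # translating one set by v moves the distance by at most |v|
    v <- c(2, 1)
    bshift <- cbind(row = b[, 1] + v[1], col = b[, 2] + v[2])
    expect_lte(abs(hausdorff_distance(a, bshift) - hausdorff_distance(a, b)),
               sqrt(sum(v^2)) + 1e-12)
  }
  empty <- matrix(0L, 4, 4); filled <- matrix(0L, 4, 4); filled[2, 2] <- 1L
  expect_error(hausdorff_distance(empty, filled), "empty prediction")
  expect_error(hausdorff_distance(filled, empty), "empty truth")
})

test_that("evaluate_masks fills all seven metrics with qualitative bands", {
  truth <- matrix(0L, 16, 16); truth[5:9, ] <- 1L
  rep1 <- evaluate_masks(truth, truth)
  expect_equal(rep1$dice, 1)
  expect_equal(rep1$hausdorff, 0)
  expect_equal(unname(rep1$bands[["dice"]]), "excellent")
  expect_equal(unname(rep1$bands[["hausdorff"]]), "good")
  expect_equal(performance_band(0.5, "mae"), "good")
  expect_equal(performance_band(1.2, "mae"), "acceptable")
  expect_equal(performance_band(40, "hausdorff"), "acceptable")
  expect_equal(performance_band(10, "hausdorff"), "good")
  expect_equal(performance_band(0.85, "overlap"), "good")
  expect_equal(performance_band(0.72, "overlap"), "acceptable")
  expect_equal(performance_band(0.95, "overlap"), "excellent")
  expect_equal(performance_band(0.5, "overlap"), "poor")
})

test_that("directory evaluation writes per-image, mean and pooled rows", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "pred")); dir.create(file.path(td, "truth"))
  set.seed(21)
  for (i in 1:3) {
    t <- matrix(0L, 16, 16); t[4:8, ] <- 1L
    p <- t; if (i > 1) p[4, ] <- 0L
    octunet:::write_mask_png(p, file.path(td, "pred", sprintf("m%d.png", i)))
    octunet:::write_mask_png(t, file.path(td, "truth", sprintf("m%d.png", i)))
  }
  tab <- evaluate_mask_dirs(file.path(td, "pred"), file.path(td, "truth"))
  expect_equal(nrow(tab), 5)
  expect_true(all(c("mean", "pooled") %in% tab$image))
  expect_equal(tab$dice[tab$image == "m1.png"], 1)
  expect_named(tab, c("image", "accuracy", "precision", "recall", "jaccard",
                      "dice", "mae", "hausdorff"))
})
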