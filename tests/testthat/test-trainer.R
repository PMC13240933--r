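test_that("splits honour the 80/20 convention and partition arithmetic", {
  items <- sprintf("im%02d", 1:60)
  sp <- split_dataset(items, seed = 3)
  expect_equal(length(sp$test), 12)
  expect_equal(length(sp$train) + length(sp$val), 48)
  expect_setequal(c(sp$train, sp$val, sp$test), items)
  # 10 items, test 0.20, val 0.25 of the remainder -> 6/2/2
  sp2 <- split_dataset(letters[1:10], test_fraction = 0.2,
                       validation_fraction = 0.25, seed = 1)
  expect_equal(lengths(sp2[c("train", "val", "test")]),
               c(train = 6L, val = 2L, test = 2L))
  expect_identical(split_dataset(items, seed = 7), split_dataset(items, seed = 7))
  expect_error(split_dataset(letters[1:4]), "at least 5")
})

test_that("no test item ever leaks into train or validation", {
  items <- sprintf("im%02d", 1:60)
  for (seed in 1:25) {
    sp <- split_dataset(items, seed = seed)
    expect_length(intersect(sp$test, c(sp$train, sp$val)), 0)
    expect_length(intersect(sp$train, sp$val), 0)
  }
})

test_that("prepare_pair keeps masks binary through resizing", {
  big <- matrix(0L, 464, 1356); big[101:120, ] <- 1L
  img <- matrix(runif(464 * 1356), 464, 1356)
  pp <- prepare_pair(img, big, c(256, 256))
  expect_true(all(pp$mask %in% c(0L, 1L)))
  expect_equal(dim(pp$mask), c(256, 256))
  expect_true(all(pp$image >= 0 & pp$image <= 1))
  # 20-px band in 464 rows lands near 20 * 256/464 = 11 px
  expect_lte(abs(sum(pp$mask[, 10]) - 11), 1)
  # identity resize is a no-op on the mask
  small <- matrix(0L, 32, 32); small[5:9, ] <- 1L
  pp2 <- prepare_pair(matrix(0.5, 32, 32), small, c(32, 32))
  expect_identical(pp2$mask, small)
  expect_error(prepare_pair(img, img, c(64, 64)), "binary")
})

test_that("training histories are bookkept per epoch with non-increasing lr", {
  ds <- tiny_dataset(8)
  sp <- split_dataset(names(ds), seed = 1)
  cfg <- train_config(image_size = c(32, 32), batch_size = 2, epochs = 1,
                      init_seed = 4)
  m <- build_unet(unet_config(32, 32, base_filters = 2), seed = 4)
  run <- train_unet(m, ds, sp, cfg)
  expect_equal(nrow(run$history), 1)
  expect_named(run$history, c("epoch", "train_loss", "train_acc",
                              "val_loss", "val_acc", "lr"))
  cfg5 <- train_config(image_size = c(32, 32), batch_size = 2, epochs = 5,
                       init_seed = 4)
  run5 <- train_unet(m, ds, sp, cfg5)
  h <- run5$history
  expect_equal(nrow(h), run5$stopped_epoch)
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  expect_true(all(h$val_acc >= 0 & h$val_acc <= 1))
  expect_true(all(h$train_loss >= 0))
  expect_true(all(diff(h$lr) <= 0))
  # the toy problem is learnable: loss drops below its first-epoch value
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("training is reproducible for fixed seeds", {
  ds <- tiny_dataset(6)
  sp <- split_dataset(names(ds), seed = 2)
  cfg <- train_config(image_size = c(32, 32), batch_size = 2, epochs = 2,
                      init_seed = 9)
  m <- build_unet(unet_config(32, 32, base_filters = 2), seed = 9)
  r1 <- train_unet(m, ds, sp, cfg)
  r2 <- train_unet(m, ds, sp, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("stagnant validation loss triggers early stopping", {
  ds <- tiny_dataset(6)
  sp <- split_dataset(names(ds), seed = 2)
  # learning rate so small the model is effectively frozen
  cfg <- train_config(image_size = c(32, 32), batch_size = 2, epochs = 20,
                      learning_rate = 1e-30, early_stop_patience = 2,
                      init_seed = 1)
  m <- build_unet(unet_config(32, 32, base_filters = 2), seed = 1)
  run <- train_unet(m, ds, sp, cfg)
  expect_lte(run$stopped_epoch, 3)
})

test_that("configuration errors are caught before training", {
  ds <- tiny_dataset(6)
  sp <- split_dataset(names(ds), seed = 2)
  m <- build_unet(unet_config(32, 32, base_filters = 2), seed = 1)
  cfg <- train_config(image_size = c(64, 64))
  expect_error(train_unet(m, ds, sp, cfg), "does not match")
  sp_bad <- sp; sp_bad$val <- character(0)
  cfg_ok <- train_config(image_size = c(32, 32))
  expect_error(train_unet(m, ds, sp_bad, cfg_ok), "empty train or validation")
  expect_error(train_config(validation_fraction = 0), "validation_fraction")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = -1), "learning_rate")
})

test_that("the overfit rule flags divergence and only divergence", {
  # parallel decrease at constant small offset: not overfitting
  par <- data.frame(train_loss = seq(1.0, 0.2, length.out = 10),
                    val_loss = seq(1.05, 0.25, length.out = 10))
  expect_false(detect_overfit(par, gap_margin = 0.1, trend_window = 5)$overfit)
  # identical curves: zero gap
  same <- data.frame(train_loss = seq(1, 0.1, length.out = 8),
                     val_loss = seq(1, 0.1, length.out = 8))
  expect_false(detect_overfit(same, trend_window = 5)$overfit)
  # training falls 1.0 -> 0.1 while validation climbs 0.5 -> 0.9
  div <- data.frame(train_loss = seq(1.0, 0.1, length.out = 10),
                    val_loss = seq(0.5, 0.9, length.out = 10))
  ov <- detect_overfit(div, gap_margin = 0.1, trend_window = 5)
  expect_true(ov$overfit)
  expect_gt(ov$val_slope, 0)
  expect_lte(ov$train_slope, 0)
  expect_match(ov$text, "overfitting")
  expect_error(detect_overfit(div[1:3, ], trend_window = 5), "trend_window")
})
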