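#' Training configuration
#'
#' Hyperparameters of the optimization loop: Adam with pixel-wise binary
#' cross-entropy loss, early stopping on validation loss and
#' reduce-on-plateau learning-rate adjustment. The logged "accuracy" is
#' pixel accuracy of the thresholded prediction.
#'
#' @param image_size Integer `(height, width)` the model operates at.
#' @param batch_size Images per gradient step; default 2.
#' @param epochs Maximum epochs; default 50.
#' @param learning_rate Adam step size; default 0.001.
#' @param validation_fraction Fraction of the non-test items held out for
#'   internal validation; default 0.2.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping; default 10.
#' @param lr_reduce_factor Multiplier applied to the learning rate on
#'   plateau; default 0.5.
#' @param lr_reduce_patience Stagnant epochs before the learning rate is
#'   reduced; default 5.
#' @param split_seed,init_seed Seeds for the dataset split and for weight
#'   initialization / batch shuffling.
#' @param binarize_threshold Probability threshold for pixel accuracy and
#'   predicted masks; default 0.5.
#' @return Object of class `train_config`.
#' @export
train_config <- function(image_size = c(256L, 256L), batch_size = 2L,
                         epochs = 50L, learning_rate = 0.001,
                         validation_fraction = 0.2,
                         early_stop_patience = 10L,
                         lr_reduce_factor = 0.5, lr_reduce_patience = 5L,
                         split_seed = 1L, init_seed = 2L,
                         binarize_threshold = 0.5) {
  stopifnot(length(image_size) == 2L, all(image_size >= 4))
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("train_config: epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("train_config: validation_fraction must be strictly between 0 and 1",
         call. = FALSE)
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1)
    stop("train_config: lr_reduce_factor must be in (0, 1)", call. = FALSE)
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stop("train_config: binarize_threshold must be in (0, 1)", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 split_seed = as.integer(split_seed),
                 init_seed = as.integer(init_seed),
                 binarize_threshold = binarize_threshold),
            class = "train_config")
}

#' Split dataset items into train / validation / test partitions
#'
#' Test items are drawn first (default 20%, so 60 items give the 48/12
#' train+validation/test convention); the validation set is then a fraction
#' of the remainder. Partitions are pairwise disjoint, cover all items, and
#' are deterministic for a fixed seed. Test items are never touched during
#' training or validation.
#'
#' @param items Vector of dataset item identifiers (>= 5).
#' @param test_fraction Fraction reserved for testing; default 0.20.
#' @param validation_fraction Fraction of the remainder used for
#'   validation; default 0.2.
#' @param seed Integer seed.
#' @return Object of class `split_result`: list with `train`, `val`,
#'   `test`.
#' @export
split_dataset <- function(items, test_fraction = 0.20,
                          validation_fraction = 0.2, seed = 1L) {
  n <- length(items)
  if (n < 5L)
    stop("split_dataset: need at least 5 items to form train/val/test partitions",
         call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(items)
    n_test <- max(1L, round(n * test_fraction))
    rest <- shuffled[-seq_len(n_test)]
    n_val <- max(1L, round(length(rest) * validation_fraction))
    if (length(rest) - n_val < 1L)
      stop("split_dataset: too few items left for a training partition", call. = FALSE)
    structure(list(train = rest[-seq_len(n_val)],
                   val = rest[seq_len(n_val)],
                   test = shuffled[seq_len(n_test)]),
              class = "split_result")
  })
}

#' Resize and normalize an image/mask pair for training
#'
#' The image is resized with bilinear interpolation and linearly scaled to
#' \[0, 1\]; the mask is resized with nearest-neighbour interpolation (and
#' defensively re-binarized at 0.5) so it remains strictly binary.
#'
#' @param image Numeric intensity matrix.
#' @param mask Binary 0/1 matrix, same shape.
#' @param target_size Integer `(height, width)`.
#' @return List with resized `image` (in \[0, 1\]) and integer `mask`.
#' @export
prepare_pair <- function(image, mask, target_size) {
  check_same_shape(image, mask, "prepare_pair")
  if (!all(is.finite(image))) stop("prepare_pair: image has non-finite values",
                                   call. = FALSE)
  check_binary_mask(mask, "mask")
  th <- as.integer(target_size[1]); tw <- as.integer(target_size[2])
  if (!identical(dim(image), c(th, tw))) {
    image <- EBImage::resize(image, w = th, h = tw, filter = "bilinear")
    mask <- EBImage::resize(matrix(as.numeric(mask), nrow(mask)), w = th, h = tw,
                            filter = "none")
  }
  if (max(image) > 1) image <- image / max(image)
  image <- pmin(pmax(image, 0), 1)
  m <- matrix(0L, th, tw)
  m[mask >= 0.5] <- 1L
  list(image = image, mask = m)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

eval_pair <- function(model, image, mask, threshold) {
  fw <- unet_forward(model, image)
  loss <- bce_from_logits(fw$logits, mask)
  acc <- mean((fw$prob >= threshold) == (mask > 0))
  list(loss = loss, acc = acc)
}

#' Train a U-Net on image/mask pairs
#'
#' Minimizes pixel-wise binary cross-entropy with Adam. Per epoch, the
#' training items are shuffled and consumed in mini-batches; training loss
#' and pixel accuracy are averaged over batches (computed before each
#' update), validation metrics are computed at epoch end. The learning rate
#' is multiplied by `lr_reduce_factor` after `lr_reduce_patience` epochs
#' without validation-loss improvement, and training stops early after
#' `early_stop_patience` such epochs. The weights from the
#' best-validation-loss epoch are returned.
#'
#' @param model A [build_unet()] model whose input size equals
#'   `config$image_size`.
#' @param dataset Named list of items, each a list with `image` and `mask`
#'   (any size; pairs are passed through [prepare_pair()]).
#' @param split A [split_dataset()] result whose identifiers index
#'   `dataset`.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return Object of class `training_run`: list with `model` (best
#'   checkpoint), `history` (`data.frame`: epoch, train_loss, train_acc,
#'   val_loss, val_acc, lr), `stopped_epoch`, `best_epoch`, `config`.
#' @export
train_unet <- function(model, dataset, split, config, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(split$train) == 0L || length(split$val) == 0L)
    stop("train_unet: empty train or validation partition", call. = FALSE)
  cfg <- model$config
  if (cfg$input_height != config$image_size[1] ||
      cfg$input_width != config$image_size[2])
    stop(sprintf("train_unet: model input %dx%d does not match config image_size %dx%d",
                 cfg$input_height, cfg$input_width,
                 config$image_size[1], config$image_size[2]), call. = FALSE)
  prep <- function(ids) lapply(dataset[ids], function(it)
    prepare_pair(it$image, it$mask, config$image_size))
  tr <- prep(split$train); va <- prep(split$val)

  state <- adam_init(model$params)
  lr <- config$learning_rate
  t_step <- 0L
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  stagnant <- 0L; lr_stagnant <- 0L
  hist <- list()
  thr <- config$binarize_threshold

  withr::with_seed(config$init_seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(seq_along(tr))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_acc <- 0
      for (bt in batches) {
        gacc <- NULL
        bl <- 0; ba <- 0
        for (i in bt) {
          fw <- unet_forward(model, tr[[i]]$image, cache = TRUE)
          y <- tr[[i]]$mask
          bl <- bl + bce_from_logits(fw$logits, y)
          ba <- ba + mean((fw$prob >= thr) == (y > 0))
          glog <- (fw$prob - y) / length(y)
          g <- unet_backward(model, fw, glog)
          gacc <- if (is.null(gacc)) g else
            Map(function(a, b) list(gW = a$gW + b$gW, gb = a$gb + b$gb), gacc, g)
        }
        nb <- length(bt)
        gacc <- lapply(gacc, function(g) list(gW = g$gW / nb, gb = g$gb / nb))
        t_step <- t_step + 1L
        upd <- adam_step(model$params, gacc, state, lr, t_step)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bl / nb; ep_acc <- ep_acc + ba / nb
      }
      n_batches <- length(batches)
      vm <- vapply(va, function(it)
        unlist(eval_pair(model, it$image, it$mask, thr)), numeric(2))
      val_loss <- mean(vm["loss", ]); val_acc <- mean(vm["acc", ])
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / n_batches,
                                  train_acc = ep_acc / n_batches,
                                  val_loss = val_loss, val_acc = val_acc,
                                  lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.4f | val loss %.4f acc %.4f | lr %g",
                        epoch, ep_loss / n_batches, ep_acc / n_batches,
                        val_loss, val_acc, lr))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_params <- model$params; best_epoch <- epoch
        stagnant <- 0L; lr_stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L; lr_stagnant <- lr_stagnant + 1L
      }
      if (lr_stagnant >= config$lr_reduce_patience) {
        lr <- lr * config$lr_reduce_factor
        lr_stagnant <- 0L
      }
      if (stagnant >= config$early_stop_patience) break
    }
  })
  model$params <- best_params
  structure(list(model = model,
                 history = do.call(rbind, hist),
                 stopped_epoch = length(hist),
                 best_epoch = best_epoch,
                 config = config),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("training_run: %d epochs (best epoch %d), final val loss %.4f, val acc %.4f\n",
              x$stopped_epoch, x$best_epoch,
              h$val_loss[nrow(h)], h$val_acc[nrow(h)]))
  invisible(x)
}

ls_slope <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Diagnose overfitting from training curves
#'
#' Flags the classic divergence signature: the final validation loss
#' exceeds the final training loss by more than `gap_margin`, while over
#' the last `trend_window` epochs the validation loss trends upward
#' (least-squares slope > 0) and the training loss does not (slope <= 0).
#'
#' @param history A `training_run`, or a `data.frame` with `train_loss`
#'   and `val_loss` columns.
#' @param gap_margin Minimum final val - train loss gap; default 0.1.
#' @param trend_window Epochs used for the trend slopes; default 5.
#' @return List with `overfit` (logical), `gap`, `val_slope`,
#'   `train_slope`, `text` (diagnostic sentence).
#' @export
detect_overfit <- function(history, gap_margin = 0.1, trend_window = 5L) {
  h <- if (inherits(history, "training_run")) history$history else history
  stopifnot(all(c("train_loss", "val_loss") %in% names(h)))
  n <- nrow(h)
  if (n < trend_window)
    stop(sprintf("detect_overfit: history has %d epochs but trend_window is %d",
                 n, trend_window), call. = FALSE)
  tail_idx <- (n - trend_window + 1L):n
  gap <- h$val_loss[n] - h$train_loss[n]
  vs <- ls_slope(h$val_loss[tail_idx])
  ts <- ls_slope(h$train_loss[tail_idx])
  flag <- (gap > gap_margin) && (vs > 0) && (ts <= 0)
  txt <- if (flag) {
    sprintf(paste0("overfitting: validation loss exceeds training loss by %.3f ",
                   "and rises (slope %.2g) while training loss does not (slope %.2g)"),
            gap, vs, ts)
  } else {
    sprintf("no overfitting signature (gap %.3f, val slope %.2g, train slope %.2g)",
            gap, vs, ts)
  }
  list(overfit = flag, gap = gap, val_slope = vs, train_slope = ts, text = txt)
}

#' Write a training history to CSV
#'
#' @param run A `training_run` (or its `history` data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(run, path) {
  h <- if (inherits(run, "training_run")) run$history else run
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
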