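#' Hyperparameter sweep configuration
#'
#' Defines the grid of the image-size x batch-size x epoch study. The
#' default axes are the four study sizes (256x256, 512x512, 1024x1024,
#' 464x1356), batch sizes 2/4/8/16 and 50/100/150 epochs — a 48-cell grid.
#' An `explicit` list of configurations overrides grid expansion.
#'
#' @param image_sizes List of `(height, width)` integer pairs.
#' @param batch_sizes Integer vector.
#' @param epoch_counts Integer vector.
#' @param explicit Optional `data.frame` with columns `height`, `width`,
#'   `batch_size`, `epochs`, taken verbatim (in order) instead of the grid.
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(image_sizes = list(c(256L, 256L), c(512L, 512L),
                                            c(1024L, 1024L), c(464L, 1356L)),
                         batch_sizes = c(2L, 4L, 8L, 16L),
                         epoch_counts = c(50L, 100L, 150L),
                         explicit = NULL) {
  if (is.null(explicit) &&
      (length(image_sizes) == 0L || length(batch_sizes) == 0L ||
       length(epoch_counts) == 0L))
    stop("sweep_config: empty sweep axes", call. = FALSE)
  structure(list(image_sizes = image_sizes, batch_sizes = batch_sizes,
                 epoch_counts = epoch_counts, explicit = explicit),
            class = "sweep_config")
}

config_label <- function(h, w, b, e) sprintf("PS_%dx%d_B%d_E%d", h, w, b, e)

#' Expand a sweep configuration into an ordered configuration table
#'
#' The Cartesian product is enumerated size-major: image size varies
#' slowest, then batch size, then epochs. Each row gets a `config_name`
#' label of the form `PS_{h}x{w}_B{b}_E{e}`.
#'
#' @param sweep A [sweep_config()].
#' @return `data.frame` with columns `config_name`, `height`, `width`,
#'   `batch_size`, `epochs`.
#' @export
expand_grid_configs <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_config"))
  if (!is.null(sweep$explicit)) {
    g <- sweep$explicit
    stopifnot(all(c("height", "width", "batch_size", "epochs") %in% names(g)))
  } else {
    rows <- list()
    for (sz in sweep$image_sizes)
      for (b in sweep$batch_sizes)
        for (e in sweep$epoch_counts)
          rows[[length(rows) + 1L]] <- data.frame(height = sz[1], width = sz[2],
                                                  batch_size = b, epochs = e)
    g <- do.call(rbind, rows)
  }
  g$config_name <- config_label(g$height, g$width, g$batch_size, g$epochs)
  dup <- g$config_name[duplicated(g$config_name)]
  if (length(dup) > 0L)
    stop(sprintf("expand_grid_configs: duplicate configurations: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  g[, c("config_name", "height", "width", "batch_size", "epochs")]
}

# Reflection-pad a matrix up to the next multiple of `div` in each
# dimension; returns the padded matrix and the original extent.
pad_to_divisible <- function(m, div) {
  H <- nrow(m); W <- ncol(m)
  ph <- (div - H %% div) %% div
  pw <- (div - W %% div) %% div
  if (ph > 0L) m <- rbind(m, m[H:(H - ph + 1L), , drop = FALSE])
  if (pw > 0L) m <- cbind(m, m[, W:(W - pw + 1L), drop = FALSE])
  list(m = m, H = H, W = W, padded = ph > 0L || pw > 0L)
}

#' Run a hyperparameter sweep on a dataset
#'
#' One shared split (identical across every configuration) is drawn from
#' the item identifiers; each configuration resizes the data to its image
#' size, trains a fresh U-Net, attaches the overfit diagnosis and
#' evaluates all seven metrics on the fixed test partition (per-image
#' means). Image sizes not divisible by `2^encoder_depth` are
#' reflection-padded before the model is built and predictions are cropped
#' back. A failing configuration is recorded with `status = "failed"` and
#' the sweep continues.
#'
#' @param configs Configuration table from [expand_grid_configs()].
#' @param dataset Named list of items (`image`, `mask`), as for
#'   [train_unet()].
#' @param base_filters,encoder_depth Architecture shared by every
#'   configuration.
#' @param split_seed,init_seed Shared seeds.
#' @param learning_rate,validation_fraction,early_stop_patience Training
#'   settings forwarded to [train_config()].
#' @param verbose Print progress.
#' @return Object of class `sweep_result`: list with `rows` (a
#'   `data.frame`, one row per configuration: the seven metrics, final
#'   losses, overfit flag, wall time, status), `split`, `test_hash` (a
#'   digest of the sorted test identifiers), and `runs` (training
#'   histories).
#' @export
run_sweep <- function(configs, dataset, base_filters = 8L, encoder_depth = 2L,
                      split_seed = 1L, init_seed = 2L,
                      learning_rate = 0.001, validation_fraction = 0.2,
                      early_stop_patience = 10L, verbose = FALSE) {
  split <- split_dataset(names(dataset), test_fraction = 0.2,
                         validation_fraction = validation_fraction,
                         seed = split_seed)
  test_hash <- paste(sort(split$test), collapse = "|")
  rows <- list(); runs <- list()
  div <- 2L^encoder_depth
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    t0 <- proc.time()["elapsed"]
    res <- tryCatch({
      ph <- as.integer(ceiling(cf$height / div) * div)
      pw <- as.integer(ceiling(cf$width / div) * div)
      padded <- ph != cf$height || pw != cf$width
      mcfg <- unet_config(ph, pw, encoder_depth = encoder_depth,
                          base_filters = base_filters)
      model <- build_unet(mcfg, seed = init_seed)
      tcfg <- train_config(image_size = c(cf$height, cf$width),
                           batch_size = cf$batch_size, epochs = cf$epochs,
                           learning_rate = learning_rate,
                           validation_fraction = validation_fraction,
                           early_stop_patience = early_stop_patience,
                           split_seed = split_seed, init_seed = init_seed)
      ds <- dataset
      if (padded) {
        ds <- lapply(dataset, function(it) {
          pp <- prepare_pair(it$image, it$mask, c(cf$height, cf$width))
          list(image = pad_to_divisible(pp$image, div)$m,
               mask = pad_to_divisible(pp$mask, div)$m)
        })
        tcfg$image_size <- c(ph, pw)
      }
      run <- train_unet(model, ds, split, tcfg, verbose = verbose)
      ov <- detect_overfit(run, trend_window = min(5L, run$stopped_epoch))
      mets <- sapply(split$test, function(id) {
        pp <- prepare_pair(dataset[[id]]$image, dataset[[id]]$mask,
                           c(cf$height, cf$width))
        img <- pp$image; msk <- pp$mask
        if (padded) img <- pad_to_divisible(img, div)$m
        prob <- unet_predict(run$model, img)
        if (padded) prob <- prob[seq_len(cf$height), seq_len(cf$width)]
        rep_i <- evaluate_masks(binarize(prob, tcfg$binarize_threshold), msk)
        c(accuracy = rep_i$accuracy, precision = rep_i$precision,
          recall = rep_i$recall, jaccard = rep_i$jaccard, dice = rep_i$dice,
          mae = rep_i$mae, hausdorff = rep_i$hausdorff)
      })
      mm <- rowMeans(mets, na.rm = TRUE)
      h <- run$history
      list(row = data.frame(config_name = cf$config_name, t(mm),
                            final_train_loss = h$train_loss[nrow(h)],
                            final_val_loss = h$val_loss[nrow(h)],
                            overfit_flag = ov$overfit,
                            n_parameters = count_parameters(run$model),
                            padded = padded,
                            wall_time_s = unname(proc.time()["elapsed"] - t0),
                            status = "ok"),
           run = run)
    }, error = function(e) {
      list(row = data.frame(config_name = cf$config_name, accuracy = NA_real_,
                            precision = NA_real_, recall = NA_real_,
                            jaccard = NA_real_, dice = NA_real_, mae = NA_real_,
                            hausdorff = NA_real_, final_train_loss = NA_real_,
                            final_val_loss = NA_real_, overfit_flag = NA,
                            n_parameters = NA_integer_, padded = NA,
                            wall_time_s = unname(proc.time()["elapsed"] - t0),
                            status = paste0("failed: ", conditionMessage(e))),
           run = NULL)
    })
    rows[[i]] <- res$row
    runs[[cf$config_name]] <- res$run
    if (verbose) message(sprintf("[%d/%d] %s: %s", i, nrow(configs),
                                 cf$config_name, res$row$status))
  }
  structure(list(rows = do.call(rbind, rows), split = split,
                 test_hash = test_hash, runs = runs),
            class = "sweep_result")
}

#' Select the best configuration from sweep results
#'
#' Default criterion: maximum Dice, with ties broken by higher Jaccard,
#' then lower Hausdorff distance, then fewer parameters. Alternatives:
#' minimum final validation loss (`"val_loss"`) or minimum MAE (`"mae"`).
#'
#' @param rows A `sweep_result` or its `rows` data.frame.
#' @param criterion `"dice"`, `"val_loss"` or `"mae"`.
#' @return List with `config_name`, `criterion`, and `comparison` (the
#'   successful rows ordered by the decision rule).
#' @export
select_best <- function(rows, criterion = c("dice", "val_loss", "mae")) {
  criterion <- match.arg(criterion)
  tab <- if (inherits(rows, "sweep_result")) rows$rows else rows
  ok <- tab[tab$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("select_best: no successful sweep rows", call. = FALSE)
  npar <- if ("n_parameters" %in% names(ok)) ok$n_parameters else rep(0L, nrow(ok))
  ord <- switch(criterion,
    dice = order(-ok$dice, -ok$jaccard, ok$hausdorff, npar),
    val_loss = order(ok$final_val_loss),
    mae = order(ok$mae))
  ok <- ok[ord, , drop = FALSE]
  list(config_name = ok$config_name[1L], criterion = criterion,
       comparison = ok)
}

#' Write sweep results to CSV
#'
#' Column layout mirrors the per-configuration results tables of the
#' hyperparameter study: metrics, final losses, overfit/converged status.
#'
#' @param sweep A `sweep_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_results <- function(sweep, path) {
  cols <- c("config_name", "accuracy", "precision", "recall", "jaccard",
            "dice", "mae", "hausdorff", "final_train_loss", "final_val_loss",
            "overfit_flag", "status")
  utils::write.csv(sweep$rows[, cols], path, row.names = FALSE)
  invisible(path)
}
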