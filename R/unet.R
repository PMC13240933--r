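#' U-Net architecture configuration
#'
#' Describes a compact encoder-decoder U-Net for binary (epidermis vs
#' background) segmentation: `encoder_depth` encoder blocks of two 3x3
#' "same"-padded convolutions + ReLU followed by 2x2 max pooling, a
#' bottleneck block, and a mirrored decoder whose blocks upsample with a
#' learned 2x2 stride-2 transposed convolution, concatenate the matching
#' encoder output through a skip connection, and apply two further 3x3
#' convolutions. A final 1x1 convolution with a sigmoid produces a one-channel
#' probability map the same size as the input.
#'
#' Channel counts double per level: `base_filters` in the first block, twice
#' that in the second, and `base_filters * 2^encoder_depth` in the bottleneck.
#'
#' @param input_height,input_width Input raster size in pixels; each must be
#'   divisible by `2^encoder_depth` so the pool/upsample round trip restores
#'   the original shape.
#' @param encoder_depth Number of encoder (and decoder) blocks; default 2.
#' @param base_filters Feature channels in the first encoder block; default 8.
#' @param upsample_kernel Spatial size of the learned upsampling filter
#'   (fixed at 2).
#' @param padding_mode Convolution padding; only `"same"` is supported, which
#'   zero-pads so spatial size is preserved within a block.
#' @param output_channels Number of output channels (fixed at 1).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_height, input_width, encoder_depth = 2L,
                        base_filters = 8L, upsample_kernel = 2L,
                        padding_mode = "same", output_channels = 1L) {
  encoder_depth <- as.integer(encoder_depth)
  base_filters <- as.integer(base_filters)
  if (encoder_depth < 1L) stop("unet_config: encoder_depth must be >= 1", call. = FALSE)
  if (base_filters < 1L) stop("unet_config: base_filters must be >= 1", call. = FALSE)
  if (upsample_kernel != 2L)
    stop("unet_config: only a 2x2 upsampling kernel is supported", call. = FALSE)
  if (!identical(padding_mode, "same"))
    stop("unet_config: only 'same' padding is supported", call. = FALSE)
  if (output_channels != 1L)
    stop("unet_config: only single-channel output is supported", call. = FALSE)
  div <- 2L^encoder_depth
  if (input_height %% div != 0L || input_width %% div != 0L)
    stop(sprintf(paste0("unet_config: input dimensions %dx%d must be divisible ",
                        "by 2^encoder_depth = %d"),
                 input_height, input_width, div), call. = FALSE)
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 encoder_depth = encoder_depth,
                 base_filters = base_filters,
                 upsample_kernel = 2L,
                 padding_mode = "same",
                 output_channels = 1L),
            class = "unet_config")
}

#' Build a U-Net model with freshly initialized weights
#'
#' Weights use He-style initialization (zero-mean normal with variance
#' `2 / fan_in`); biases start at zero. Given the same `config` and `seed`
#' the built model is bit-identical.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet_model`: list with `config` and `params`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  withr::with_seed(as.integer(seed), {
    d <- config$encoder_depth
    f <- config$base_filters
    params <- list()
    he_conv3 <- function(cin, cout) {
      list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                      9L * cin, cout),
           b = numeric(cout), type = "conv3")
    }
    he_up <- function(cin, cout) {
      list(W = array(stats::rnorm(4L * cin * cout, 0, sqrt(2 / (4 * cin))),
                     c(2L, 2L, cin, cout)),
           b = numeric(cout), type = "upconv")
    }
    cin <- 1L
    for (l in seq_len(d)) {
      fl <- f * 2L^(l - 1L)
      params[[sprintf("enc%d_conv1", l)]] <- he_conv3(cin, fl)
      params[[sprintf("enc%d_conv2", l)]] <- he_conv3(fl, fl)
      cin <- fl
    }
    fb <- f * 2L^d
    params[["bott_conv1"]] <- he_conv3(cin, fb)
    params[["bott_conv2"]] <- he_conv3(fb, fb)
    cin <- fb
    for (l in rev(seq_len(d))) {
      fl <- f * 2L^(l - 1L)
      params[[sprintf("up%d", l)]] <- he_up(cin, fl)
      params[[sprintf("dec%d_conv1", l)]] <- he_conv3(2L * fl, fl)
      params[[sprintf("dec%d_conv2", l)]] <- he_conv3(fl, fl)
      cin <- fl
    }
    params[["out_conv"]] <- list(W = matrix(stats::rnorm(f, 0, sqrt(2 / f)), f, 1L),
                                 b = 0, type = "conv1")
    structure(list(config = config, params = params), class = "unet_model")
  })
}

#' Count trainable parameters of a U-Net
#'
#' @param model A [build_unet()] model.
#' @return Integer total of all weight and bias entries.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("unet_model: %dx%d input, depth %d, base filters %d, %s parameters\n",
              cfg$input_height, cfg$input_width, cfg$encoder_depth,
              cfg$base_filters, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Full forward pass. With cache = TRUE every intermediate needed for
# backpropagation is retained. skip_scale multiplies each skip connection
# (1 = normal wiring; 0 ablates a connection, used to assert liveness).
unet_forward <- function(model, x, cache = FALSE, skip_scale = NULL) {
  cfg <- model$config
  p <- model$params
  d <- cfg$encoder_depth
  if (is.null(skip_scale)) skip_scale <- rep(1, d)
  cur <- as_hwc(x)
  cs <- list()

  conv_block <- function(cur, n1, n2) {
    if (cache) {
      f1 <- conv3_forward(cur, p[[n1]]$W, p[[n1]]$b, cache = TRUE)
      a1 <- relu(f1$out)
      f2 <- conv3_forward(a1, p[[n2]]$W, p[[n2]]$b, cache = TRUE)
      a2 <- relu(f2$out)
      list(out = a2, c1 = f1, c2 = f2, pre1 = f1$out, pre2 = f2$out)
    } else {
      a1 <- relu(conv3_forward(cur, p[[n1]]$W, p[[n1]]$b))
      list(out = relu(conv3_forward(a1, p[[n2]]$W, p[[n2]]$b)))
    }
  }

  enc_out <- vector("list", d)
  for (l in seq_len(d)) {
    blk <- conv_block(cur, sprintf("enc%d_conv1", l), sprintf("enc%d_conv2", l))
    enc_out[[l]] <- blk$out
    pool <- maxpool2_forward(blk$out)
    if (cache) cs[[sprintf("enc%d", l)]] <- list(blk = blk, pool = pool)
    cur <- pool$out
  }

  blk <- conv_block(cur, "bott_conv1", "bott_conv2")
  if (cache) cs[["bott"]] <- list(blk = blk)
  cur <- blk$out

  for (l in rev(seq_len(d))) {
    nm <- sprintf("up%d", l)
    up <- upconv2_forward(cur, p[[nm]]$W, p[[nm]]$b, cache = cache)
    upo <- if (cache) up$out else up
    skip <- enc_out[[l]]
    if (skip_scale[l] != 1) skip <- skip * skip_scale[l]
    c1 <- dim(upo)[3]; c2 <- dim(skip)[3]
    cat_in <- array(0, c(dim(upo)[1], dim(upo)[2], c1 + c2))
    cat_in[, , seq_len(c1)] <- upo
    cat_in[, , c1 + seq_len(c2)] <- skip
    blk <- conv_block(cat_in, sprintf("dec%d_conv1", l), sprintf("dec%d_conv2", l))
    if (cache) cs[[sprintf("dec%d", l)]] <- list(up = up, blk = blk,
                                                 c1 = c1, c2 = c2,
                                                 cat_in = cat_in)
    cur <- blk$out
  }

  logits <- conv1_forward(cur, p[["out_conv"]]$W, p[["out_conv"]]$b)
  prob <- sigmoid(logits)
  if (cache) {
    cs[["final_act"]] <- cur
    list(prob = prob, logits = logits, cache = cs, skip_scale = skip_scale)
  } else {
    list(prob = prob, logits = logits)
  }
}

# Backpropagate a gradient w.r.t. the logits through the whole network.
# Returns a list of gradients mirroring model$params ($gW, $gb each).
unet_backward <- function(model, fw, glogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$encoder_depth
  cs <- fw$cache
  grads <- list()

  ob <- conv1_backward(cs[["final_act"]], p[["out_conv"]]$W, glogits)
  grads[["out_conv"]] <- list(gW = ob$gW, gb = ob$gb)
  g <- ob$gx

  block_backward <- function(blk, n1, n2, g) {
    g2 <- relu_backward(blk$pre2, g)
    b2 <- conv3_backward(blk$c2, p[[n2]]$W, g2)
    g1 <- relu_backward(blk$pre1, b2$gx)
    b1 <- conv3_backward(blk$c1, p[[n1]]$W, g1)
    list(gx = b1$gx,
         g1 = list(gW = b1$gW, gb = b1$gb),
         g2 = list(gW = b2$gW, gb = b2$gb))
  }

  gskip <- vector("list", d)
  for (l in seq_len(d)) {            # decoder blocks, reverse of forward order
    dc <- cs[[sprintf("dec%d", l)]]
    n1 <- sprintf("dec%d_conv1", l); n2 <- sprintf("dec%d_conv2", l)
    bb <- block_backward(dc$blk, n1, n2, g)
    grads[[n1]] <- bb$g1; grads[[n2]] <- bb$g2
    gcat <- bb$gx
    gup <- gcat[, , seq_len(dc$c1), drop = FALSE]
    gs <- gcat[, , dc$c1 + seq_len(dc$c2), drop = FALSE]
    if (fw$skip_scale[l] != 1) gs <- gs * fw$skip_scale[l]
    gskip[[l]] <- gs
    nm <- sprintf("up%d", l)
    ub <- upconv2_backward(dc$up, p[[nm]]$W, gup)
    grads[[nm]] <- list(gW = ub$gW, gb = ub$gb)
    g <- ub$gx
  }

  bb <- block_backward(cs[["bott"]]$blk, "bott_conv1", "bott_conv2", g)
  grads[["bott_conv1"]] <- bb$g1; grads[["bott_conv2"]] <- bb$g2
  g <- bb$gx

  for (l in rev(seq_len(d))) {       # encoder blocks, reverse of forward order
    ec <- cs[[sprintf("enc%d", l)]]
    ga <- maxpool2_backward(ec$pool, g) + gskip[[l]]
    n1 <- sprintf("enc%d_conv1", l); n2 <- sprintf("enc%d_conv2", l)
    bb <- block_backward(ec$blk, n1, n2, ga)
    grads[[n1]] <- bb$g1; grads[[n2]] <- bb$g2
    g <- bb$gx
  }
  grads
}

#' Predict a per-pixel epidermis probability map
#'
#' Runs a forward pass; output is the same size as the input with every
#' value in \[0, 1\], and is deterministic for a fixed model.
#'
#' @param model A [build_unet()] (or trained) model.
#' @param image Numeric matrix of intensities in \[0, 1\], with dimensions
#'   equal to the model's configured input size.
#' @return Numeric matrix of probabilities, same shape as `image`.
#' @export
unet_predict <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$config
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 1L)
    image <- image[, , 1L]
  if (!is.matrix(image) || nrow(image) != cfg$input_height ||
      ncol(image) != cfg$input_width)
    stop(sprintf("unet_predict: expected a %dx%d image, got %s",
                 cfg$input_height, cfg$input_width,
                 paste(dim(image), collapse = "x")), call. = FALSE)
  if (!all(is.finite(image)))
    stop("unet_predict: image contains non-finite values", call. = FALSE)
  unet_forward(model, image)$prob
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding weights and configuration; a
#' sidecar JSON (`<path>.json`) records the configuration so checkpoints are
#' self-describing.
#'
#' @param model A `unet_model`.
#' @param path Destination file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}
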