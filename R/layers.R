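# Low-level differentiable layer primitives for the U-Net.
#
# Tensors are base-R 3-d arrays (height, width, channels). The 3x3 "same"
# convolutions, ReLU and 2x2 max pooling run in compiled strip-blocked
# kernels (src/conv_kernels.cpp) with the matrix products inside BLAS; the
# 2x2 transposed convolution decomposes into four 1x1 convolutions and
# stays in R, where it is a plain GEMM per output sub-lattice.

as_hwc <- function(x) {
  if (!is.double(x)) storage.mode(x) <- "double"
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# 3x3 same convolution. W is (9*Cin) x Cout, b length Cout. The cache for
# backpropagation keeps the layer input (the patch matrix is rebuilt strip
# by strip in the backward kernel rather than stored).
conv3_forward <- function(x, W, b, cache = FALSE) {
  x <- as_hwc(x)
  d <- dim(x)
  out <- .conv3_fwd_cpp(x, W, b, d[1], d[2], d[3])
  if (cache) list(out = out, x = x, H = d[1], W = d[2], C = d[3]) else out
}

conv3_backward <- function(fw, W, gy) {
  .conv3_bwd_cpp(fw$x, gy, W, fw$H, fw$W, fw$C)
}

relu <- function(x) .relu_cpp(x)

relu_backward <- function(pre, g) .relu_bwd_cpp(pre, g)

# 2x2 max pooling, stride 2. Ties resolve deterministically to the first
# window element (top-left, below, right, diagonal order).
maxpool2_forward <- function(x) {
  d <- dim(x)
  r <- .maxpool2_cpp(x, d[1], d[2], d[3])
  list(out = r$out, idx = r$idx, H = d[1], W = d[2], C = d[3])
}

maxpool2_backward <- function(fw, g) {
  .maxpool2_bwd_cpp(g, fw$idx, fw$H, fw$W, fw$C)
}

# Learned 2x2 stride-2 transposed convolution (upsampling). Each input pixel
# paints a 2x2 output block, so the op decomposes into four 1x1 convolutions,
# one per output sub-lattice. W is a (2, 2, Cin, Cout) array.
upconv2_forward <- function(x, W, b, cache = FALSE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  Cout <- dim(W)[4]
  xm <- x
  dim(xm) <- c(H * Wd, C)
  out <- array(0, c(2L * H, 2L * Wd, Cout))
  for (a in 1:2) for (bb in 1:2) {
    Wab <- matrix(W[a, bb, , ], C, Cout)
    y <- xm %*% Wab
    for (j in seq_len(Cout)) y[, j] <- y[, j] + b[j]
    dim(y) <- c(H, Wd, Cout)
    out[seq(a, 2L * H, 2L), seq(bb, 2L * Wd, 2L), ] <- y
  }
  if (cache) list(out = out, xm = xm, H = H, W = Wd, C = C) else out
}

upconv2_backward <- function(fw, W, gy) {
  C <- fw$C; Cout <- dim(W)[4]
  gW <- array(0, dim(W))
  gb <- numeric(Cout)
  gxm <- matrix(0, fw$H * fw$W, C)
  for (a in 1:2) for (bb in 1:2) {
    gab <- gy[seq(a, 2L * fw$H, 2L), seq(bb, 2L * fw$W, 2L), , drop = FALSE]
    dim(gab) <- c(fw$H * fw$W, Cout)
    Wab <- matrix(W[a, bb, , ], C, Cout)
    gW[a, bb, , ] <- crossprod(fw$xm, gab)
    gb <- gb + colSums(gab)
    gxm <- gxm + gab %*% t(Wab)
  }
  list(gx = array(gxm, c(fw$H, fw$W, C)), gW = gW, gb = gb)
}

# Final 1x1 convolution to a single logit channel.
conv1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% W + b
  dim(y) <- c(d[1], d[2])
  y
}

conv1_backward <- function(x, W, gy) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  gym <- gy
  dim(gym) <- c(d[1] * d[2], 1L)
  gx <- gym %*% t(W)
  dim(gx) <- d
  list(gx = gx, gW = crossprod(xm, gym), gb = sum(gym))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable pixel-wise binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  # log(1 + exp(z)) - y*z, with the softplus evaluated stably
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  mean(sp - y * z)
}
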