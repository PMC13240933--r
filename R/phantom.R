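#' Specification of a synthetic OCT skin phantom
#'
#' Describes the geometry, optics and artifact content of a synthetic B-scan
#' of skin: a dark air gap, a bright entrance surface, an epidermis band of
#' spatially varying thickness bounded below by a smooth dermal-epidermal
#' junction (DEJ), an attenuating textured dermis, multiplicative speckle,
#' and (optionally) a localized hyperkeratotic thickening and vertical
#' hair-shadow artifacts.
#'
#' All geometric quantities are in pixels; `axial_pitch_um` carries the
#' depth calibration (micrometres per pixel) used when thickness is reported
#' in micrometres.
#'
#' @param height,width Canvas size in pixels (rows x columns).
#' @param surface_depth_mean Mean row index of the skin entrance surface.
#' @param surface_roughness_amplitude Peak amplitude (px) of the smooth
#'   lateral variation of the entrance surface.
#' @param epidermis_thickness_mean Mean epidermis thickness in pixels.
#' @param epidermis_thickness_amplitude Peak amplitude (px) of the smooth
#'   lateral variation of the DEJ depth (i.e. of the band thickness).
#' @param speckle_contrast Speckle contrast ratio (sd/mean of the
#'   multiplicative noise), in (0, 1]. Values near 0 give an essentially
#'   noise-free image.
#' @param attenuation_rate Per-pixel exponential intensity decay with depth
#'   below the DEJ (dermal attenuation).
#' @param hyperkeratosis_probability Probability that the phantom carries a
#'   localized hyperkeratotic region (thickened, brighter surface).
#' @param hyperkeratosis_extra_thickness Peak extra band thickness (px) of
#'   the hyperkeratotic bump.
#' @param shadow_count_mean Expected number of vertical hair shadows
#'   (Poisson distributed).
#' @param axial_pitch_um Axial pixel pitch in micrometres per pixel.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_spec <- function(height = 464, width = 1356,
                         surface_depth_mean = 60,
                         surface_roughness_amplitude = 6,
                         epidermis_thickness_mean = 34,
                         epidermis_thickness_amplitude = 10,
                         speckle_contrast = 0.35,
                         attenuation_rate = 0.004,
                         hyperkeratosis_probability = 0.3,
                         hyperkeratosis_extra_thickness = 15,
                         shadow_count_mean = 1.5,
                         axial_pitch_um = 5.5,
                         seed = 1L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    surface_depth_mean = surface_depth_mean,
    surface_roughness_amplitude = surface_roughness_amplitude,
    epidermis_thickness_mean = epidermis_thickness_mean,
    epidermis_thickness_amplitude = epidermis_thickness_amplitude,
    speckle_contrast = speckle_contrast,
    attenuation_rate = attenuation_rate,
    hyperkeratosis_probability = hyperkeratosis_probability,
    hyperkeratosis_extra_thickness = hyperkeratosis_extra_thickness,
    shadow_count_mean = shadow_count_mean,
    axial_pitch_um = axial_pitch_um,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  chk_pos <- function(field, strict = TRUE) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (strict && v <= 0) || (!strict && v < 0)) {
      stop(sprintf("phantom_spec: field '%s' must be a %s finite number",
                   field, if (strict) "strictly positive" else "non-negative"),
           call. = FALSE)
    }
  }
  for (f in c("height", "width", "surface_depth_mean",
              "epidermis_thickness_mean", "axial_pitch_um")) chk_pos(f)
  for (f in c("surface_roughness_amplitude", "epidermis_thickness_amplitude",
              "attenuation_rate", "hyperkeratosis_extra_thickness",
              "shadow_count_mean")) chk_pos(f, strict = FALSE)
  if (spec$speckle_contrast <= 0 || spec$speckle_contrast > 1)
    stop("phantom_spec: field 'speckle_contrast' must be in (0, 1]",
         call. = FALSE)
  if (spec$hyperkeratosis_probability < 0 || spec$hyperkeratosis_probability > 1)
    stop("phantom_spec: field 'hyperkeratosis_probability' must be in [0, 1]",
         call. = FALSE)
  reach <- spec$surface_depth_mean + spec$surface_roughness_amplitude +
    spec$epidermis_thickness_mean + spec$epidermis_thickness_amplitude +
    spec$hyperkeratosis_extra_thickness
  if (reach >= spec$height)
    stop(paste0("phantom_spec: fields 'surface_depth_mean' + ",
                "'epidermis_thickness_mean' (+ amplitudes and hyperkeratosis ",
                "allowance) must stay below 'height'"), call. = FALSE)
  invisible(spec)
}

#' Preset phantom specifications
#'
#' `"native"` matches the acquisition geometry of a swept-source skin OCT
#' B-scan: 464 x 1356 pixels covering a 6 mm lateral field at 4.4 um
#' fast-axis sampling, with a 5.5 um axial figure used as the depth pitch.
#' `"quick"` is a 256 x 256 canvas with proportionally scaled geometry for
#' fast experimentation and unit tests.
#'
#' @param name `"native"` or `"quick"`.
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("native", "quick"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    native = list(),
    quick = list(height = 256, width = 256,
                 surface_depth_mean = 40, surface_roughness_amplitude = 5,
                 epidermis_thickness_mean = 24,
                 epidermis_thickness_amplitude = 7,
                 attenuation_rate = 0.008,
                 hyperkeratosis_extra_thickness = 10,
                 shadow_count_mean = 1)
  )
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Smooth band-limited lateral profile: sum of a few low-frequency sinusoids
# with random phases/frequencies, normalized to peak amplitude `amplitude`.
smooth_profile <- function(width, amplitude, n_waves = 4L) {
  freq <- stats::runif(n_waves, 0.5, 4)       # cycles across the field
  phase <- stats::runif(n_waves, 0, 2 * pi)
  wgt <- stats::runif(n_waves, 0.3, 1)
  x <- seq(0, 1, length.out = width)
  g <- rep(0, width)
  for (k in seq_len(n_waves)) g <- g + wgt[k] * sin(2 * pi * freq[k] * x + phase[k])
  m <- max(abs(g))
  if (m > 0) g <- g / m
  amplitude * g
}

#' Generate one synthetic OCT B-scan with its ground-truth epidermis mask
#'
#' The phantom is layered top to bottom: near-zero air, a bright entrance
#' surface forming the top of the epidermis, a mid-intensity epidermis band
#' ending at a smooth DEJ, and a textured dermis whose intensity decays
#' exponentially with depth. Unit-mean multiplicative gamma speckle is
#' applied everywhere; hair shadows darken narrow column spans below the
#' surface. The returned mask covers exactly the epidermis band, which in
#' every column is a single contiguous vertical run whose length equals the
#' returned thickness profile.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair`: list with `image` (numeric
#'   matrix in \[0, 1\]), `mask` (integer matrix, 1 = epidermis),
#'   `thickness_px` (integer per-column thickness), `axial_pitch_um`, `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  H <- spec$height; W <- spec$width

  surface <- spec$surface_depth_mean +
    smooth_profile(W, spec$surface_roughness_amplitude)
  thick <- spec$epidermis_thickness_mean +
    smooth_profile(W, spec$epidermis_thickness_amplitude)

  # localized hyperkeratosis: raised-cosine bump added to band thickness,
  # with a matching surface brightening weight
  hk_weight <- rep(0, W)
  if (stats::runif(1) < spec$hyperkeratosis_probability &&
      spec$hyperkeratosis_extra_thickness > 0) {
    centre <- stats::runif(1, 0.15 * W, 0.85 * W)
    halfw <- stats::runif(1, W / 10, W / 4)
    x <- seq_len(W)
    inside <- abs(x - centre) < halfw
    hk_weight[inside] <- 0.5 * (1 + cos(pi * (x[inside] - centre) / halfw))
    thick <- thick + spec$hyperkeratosis_extra_thickness * hk_weight
  }

  srow <- pmax(2L, pmin(H - 2L, as.integer(round(surface))))
  tpx <- pmax(1L, as.integer(round(thick)))
  tpx <- pmin(tpx, H - srow)           # band must end inside the canvas
  dej <- srow + tpx - 1L               # last epidermis row per column

  img <- matrix(0.03, H, W)            # air background
  rows <- matrix(seq_len(H), H, W)
  srow_m <- matrix(srow, H, W, byrow = TRUE)
  dej_m <- matrix(dej, H, W, byrow = TRUE)

  in_band <- rows >= srow_m & rows <= dej_m
  img[in_band] <- 0.45
  # bright entrance surface: top 1-2 rows of the band (never thicker than it)
  surf_rows <- rows >= srow_m & rows <= pmin(srow_m + 1L, dej_m)
  bright <- 0.95 + 0.05 * matrix(hk_weight, H, W, byrow = TRUE)
  img[surf_rows] <- pmin(1, bright[surf_rows])

  # dermis: base level with low-frequency lateral/axial texture, attenuated
  below <- rows > dej_m
  depth_below <- (rows - dej_m)[below]
  tex_phase <- stats::runif(2, 0, 2 * pi)
  tex <- 1 + 0.12 * sin(2 * pi * 3 * (col(img)[below] / W) + tex_phase[1]) *
    cos(2 * pi * 6 * (rows[below] / H) + tex_phase[2])
  img[below] <- 0.55 * tex * exp(-spec$attenuation_rate * depth_below)

  # unit-mean multiplicative gamma speckle, sd = speckle_contrast
  cc <- spec$speckle_contrast
  img <- img * matrix(stats::rgamma(H * W, shape = 1 / cc^2, scale = cc^2), H, W)

  # vertical hair shadows: darken a narrow column span below the surface
  n_shadow <- stats::rpois(1, spec$shadow_count_mean)
  if (n_shadow > 0) {
    for (s in seq_len(n_shadow)) {
      wdt <- sample(3:10, 1)
      c0 <- sample.int(max(1L, W - wdt + 1L), 1)
      fac <- stats::runif(1, 0.15, 0.35)
      cols <- c0:(c0 + wdt - 1L)
      for (cc2 in cols) {
        sh_rows <- (srow[cc2] + 2L):H
        img[sh_rows, cc2] <- img[sh_rows, cc2] * fac
      }
    }
  }

  img <- pmin(pmax(img, 0), 1)
  mask <- matrix(0L, H, W)
  mask[in_band] <- 1L

  structure(list(image = img, mask = mask, thickness_px = tpx,
                 axial_pitch_um = spec$axial_pitch_um, spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("phantom_pair: %d x %d B-scan, mean thickness %.1f px (%.1f um)\n",
              nrow(x$image), ncol(x$image), mean(x$thickness_px),
              mean(x$thickness_px) * x$axial_pitch_um))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a CSV manifest. Item `i` is generated
#' from `spec` with seed `seed + i - 1`, so the dataset is a deterministic
#' function of `(n, spec, seed)`.
#'
#' @param n Number of phantoms (>= 1).
#' @param spec A [phantom_spec()]; its own `seed` field is ignored here.
#' @param seed Base seed for the dataset.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest `data.frame` with columns `image_path`,
#'   `mask_path`, `item_seed`, `mean_thickness_px`; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n, spec, seed = 1L, out_dir) {
  if (!is.numeric(n) || n < 1) stop("generate_dataset: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("generate_dataset: cannot create directory '%s'", out_dir),
                  call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    item_seed <- as.integer(seed) + i - 1L
    sp <- spec; sp$seed <- item_seed
    pair <- generate_phantom(sp)
    img_path <- file.path(out_dir, sprintf("phantom_%03d_image.png", i))
    msk_path <- file.path(out_dir, sprintf("phantom_%03d_mask.png", i))
    write_gray_png(pair$image, img_path)
    write_mask_png(pair$mask, msk_path)
    rows[[i]] <- data.frame(image_path = img_path, mask_path = msk_path,
                            item_seed = item_seed,
                            mean_thickness_px = mean(pair$thickness_px))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
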