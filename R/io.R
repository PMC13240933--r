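# Image and configuration I/O shared by the pipeline stages.

read_gray <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (PNG/TIFF only)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    chans <- lapply(seq_len(min(ch, 3L)), function(k) img[, , k])
    same <- all(vapply(chans[-1], function(m) identical(m, chans[[1]]), logical(1)))
    if (!same)
      stop(sprintf("non-grayscale input '%s': color channels differ", path),
           call. = FALSE)
    img <- chans[[1]]
  }
  img          # readPNG/readTIFF already scale 8/16-bit to [0, 1]
}

write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask)), path)
  invisible(path)
}

read_mask_png <- function(path) {
  m <- read_gray(path)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m >= 128 / 255 - 1e-9] <- 1L
  out
}

#' Load an OCT B-scan image with its epidermis mask
#'
#' Reads 8- or 16-bit grayscale PNG/TIFF files. Intensities are scaled to
#' \[0, 1\] (a 16-bit maximum of 65535 loads as 1.0). The mask is strictly
#' binarized at the 8-bit midpoint: raw values >= 128 are foreground, so
#' 127 is background.
#'
#' @param image_path,mask_path File paths; the mask must match the image
#'   shape.
#' @return List with `image` (numeric matrix in \[0, 1\]) and `mask`
#'   (integer 0/1 matrix).
#' @export
load_image_mask_pair <- function(image_path, mask_path) {
  image <- read_gray(image_path)
  mask <- read_mask_png(mask_path)
  if (!identical(dim(image), dim(mask)))
    stop(sprintf("shape mismatch: image %s is %s but mask %s is %s",
                 basename(image_path), paste(dim(image), collapse = "x"),
                 basename(mask_path), paste(dim(mask), collapse = "x")),
         call. = FALSE)
  list(image = image, mask = mask)
}

load_manifest_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_path", "mask_path") %in% names(man)))
  base <- dirname(manifest_path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  items <- lapply(seq_len(nrow(man)), function(i)
    load_image_mask_pair(fix(man$image_path[i]), fix(man$mask_path[i])))
  names(items) <- basename(man$image_path)
  items
}

#' Render a manual/automated segmentation overlay
#'
#' Writes an RGB PNG of the grayscale B-scan with manual-only pixels in
#' red, predicted-only pixels in blue, and their intersection in purple.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param manual_mask,predicted_mask Binary masks, same shape as `image`.
#' @param out_path Output PNG path.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(image, manual_mask, predicted_mask, out_path) {
  check_same_shape(image, manual_mask, "render_overlay")
  check_same_shape(image, predicted_mask, "render_overlay")
  base <- pmin(pmax(image, 0), 1) * 0.55
  r <- base; g <- base; b <- base
  r[manual_mask > 0] <- 0.85
  b[predicted_mask > 0] <- 0.85
  rgb <- array(0, c(nrow(image), ncol(image), 3L))
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, out_path)
  invisible(out_path)
}

#' Default run configuration
#'
#' The full set of tunable parameters of the pipeline with their defaults,
#' grouped into `phantom`, `model`, `train` and `sweep` sections. A YAML
#' run-configuration file may override any subset; unmentioned values keep
#' these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    phantom = unclass(phantom_preset("quick")),
    model = list(encoder_depth = 2L, base_filters = 8L,
                 upsample_kernel = 2L, padding_mode = "same"),
    train = unclass(train_config()),
    sweep = list(image_sizes = list(c(256L, 256L), c(512L, 512L),
                                    c(1024L, 1024L), c(464L, 1356L)),
                 batch_sizes = c(2L, 4L, 8L, 16L),
                 epoch_counts = c(50L, 100L, 150L))
  )
}

#' Load a YAML run configuration, merged over the defaults
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   sections; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  for (sec in intersect(names(user), names(cfg)))
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
  cfg
}

# Provenance record: configuration, seeds, package version and input
# hashes. Deliberately timestamp-free so identical runs write identical
# records.
write_provenance <- function(out_dir, config, seeds, inputs = character(0)) {
  rec <- list(package = "octunet",
              version = as.character(utils::packageVersion("octunet")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seeds = seeds, config = config,
              input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}
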