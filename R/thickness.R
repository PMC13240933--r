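#' Per-column epidermal thickness from a binary mask
#'
#' For each image column the thickness is the vertical span between the
#' upper and lower epidermal boundaries: `last foreground row - first
#' foreground row + 1` (the outer envelope, so stray multi-run columns in a
#' noisy prediction are spanned). Columns with no foreground are undefined
#' (`NA`) and excluded from the mean; `strict = TRUE` instead raises an
#' error if any column holds more than one foreground run.
#'
#' @param mask Binary 0/1 matrix (rows = depth).
#' @param axial_pitch_um Micrometres per pixel in depth; default 5.5.
#' @param strict If `TRUE`, fail on columns with multiple foreground runs.
#' @return Object of class `thickness_profile`: list with `per_column_px`
#'   (integer, `NA` where empty), `mean_px`, `mean_um`, `axial_pitch_um`,
#'   `n_defined`, `multi_run_columns` (1-based indices).
#' @export
thickness_profile <- function(mask, axial_pitch_um = 5.5, strict = FALSE) {
  check_binary_mask(mask, "mask")
  stopifnot(is.numeric(axial_pitch_um), axial_pitch_um > 0)
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask > 0
  any_fg <- colSums(fg) > 0
  if (!any(any_fg))
    stop("thickness_profile: no epidermis detected (mask is empty)", call. = FALSE)
  first <- apply(fg, 2L, function(cl) if (any(cl)) which(cl)[1L] else NA_integer_)
  last <- apply(fg, 2L, function(cl) if (any(cl)) which(cl)[sum(cl)] else NA_integer_)
  per_col <- last - first + 1L
  runs <- colSums(fg[-1L, , drop = FALSE] & !fg[-H, , drop = FALSE]) + as.integer(fg[1L, ])
  multi <- which(runs > 1L)
  if (strict && length(multi) > 0L)
    stop(sprintf("thickness_profile: columns with multiple foreground runs: %s",
                 paste(utils::head(multi, 10L), collapse = ", ")), call. = FALSE)
  mean_px <- mean(per_col, na.rm = TRUE)
  structure(list(per_column_px = as.integer(per_col),
                 mean_px = mean_px,
                 mean_um = mean_px * axial_pitch_um,
                 axial_pitch_um = axial_pitch_um,
                 n_defined = sum(any_fg),
                 multi_run_columns = multi),
            class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("thickness_profile: mean %.2f px = %.2f um (pitch %.2f um/px, %d/%d columns defined)\n",
              x$mean_px, x$mean_um, x$axial_pitch_um, x$n_defined,
              length(x$per_column_px)))
  invisible(x)
}

#' Agreement between manual and automated thickness measurements
#'
#' Bland-Altman analysis of paired measurements: bias is the mean of
#' (automated - manual) differences and the 95% limits of agreement are
#' `bias +/- 1.96 * SD` with the n-1 sample standard deviation. Pearson
#' correlation (two-sided) is computed between the paired lists; if either
#' list is constant, `r` and its p-value are `NA` with a warning.
#'
#' @param manual_um,auto_um Equal-length numeric vectors (micrometres),
#'   n >= 3.
#' @return Object of class `agreement_stats`: `bias_um`, `loa_low_um`,
#'   `loa_high_um`, `sd_diff_um`, `pearson_r`, `pearson_p`, `n`, and
#'   `points` (a `data.frame` of per-pair Bland-Altman coordinates `mean`
#'   and `difference`).
#' @export
compare_thickness <- function(manual_um, auto_um) {
  if (length(manual_um) != length(auto_um))
    stop("compare_thickness: manual and automated lists differ in length",
         call. = FALSE)
  n <- length(manual_um)
  if (n < 3L) stop("compare_thickness: need at least 3 pairs", call. = FALSE)
  d <- auto_um - manual_um
  bias <- mean(d)
  sdd <- stats::sd(d)            # n - 1 denominator
  if (stats::sd(manual_um) == 0 || stats::sd(auto_um) == 0) {
    warning("compare_thickness: constant measurements, Pearson r undefined")
    r <- NA_real_; pv <- NA_real_
  } else {
    ct <- stats::cor.test(manual_um, auto_um, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate); pv <- ct$p.value
  }
  structure(list(bias_um = bias,
                 loa_low_um = bias - 1.96 * sdd,
                 loa_high_um = bias + 1.96 * sdd,
                 sd_diff_um = sdd,
                 pearson_r = r, pearson_p = pv, n = n,
                 points = data.frame(mean = (manual_um + auto_um) / 2,
                                     difference = d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement_stats (n = %d): bias %.3f um, 95%% LoA [%.3f, %.3f] um\n",
              x$n, x$bias_um, x$loa_low_um, x$loa_high_um))
  if (!is.na(x$pearson_r))
    cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Paired comparison of segmentation metrics across B-scan positions
#'
#' Compares per-image metrics measured at the 25%, 50% and 75% slice
#' positions of an OCT volume with two-sided paired t-tests for each
#' position pair (25 vs 50, 75 vs 50, 25 vs 75). Degenerate cases are
#' reported instead of a spurious p-value: all-zero differences give
#' `p = 1` (note `"zero difference"`), constant nonzero differences give
#' `p = NA` (note `"degenerate: constant nonzero difference"`).
#'
#' @param metric_table `data.frame` with columns `image_id`, `position`
#'   (values in 25/50/75) and one column per metric.
#' @param alpha Significance level; default 0.05.
#' @return `data.frame` with one row per metric x position pair: the two
#'   position means, `p_value`, `significant`, `note`.
#' @export
position_comparison <- function(metric_table, alpha = 0.05) {
  need <- c("image_id", "position")
  if (!all(need %in% names(metric_table)))
    stop("position_comparison: metric_table needs 'image_id' and 'position' columns",
         call. = FALSE)
  metrics <- setdiff(names(metric_table), need)
  positions <- sort(unique(metric_table$position))
  ids_by_pos <- split(metric_table$image_id, metric_table$position)
  common <- Reduce(intersect, ids_by_pos)
  unmatched <- setdiff(unique(metric_table$image_id), common)
  if (length(unmatched) > 0L)
    stop(sprintf("position_comparison: images not present at every position: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  pairs <- list(c(25, 50), c(75, 50), c(25, 75))
  pairs <- Filter(function(p) all(p %in% positions), pairs)
  out <- list()
  for (m in metrics) {
    for (pr in pairs) {
      a <- metric_table[metric_table$position == pr[1], ]
      b <- metric_table[metric_table$position == pr[2], ]
      a <- a[match(common, a$image_id), m]
      b <- b[match(common, b$image_id), m]
      d <- a - b
      if (all(d == 0)) {
        pv <- 1; note <- "zero difference"
      } else if (stats::sd(d) <= 1e-10 * max(abs(d))) {
        pv <- NA_real_; note <- "degenerate: constant nonzero difference"
      } else {
        pv <- stats::t.test(a, b, paired = TRUE,
                            alternative = "two.sided")$p.value
        note <- ""
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = m, position_a = pr[1], position_b = pr[2],
        mean_a = mean(a), mean_b = mean(b),
        p_value = pv, significant = !is.na(pv) && pv < alpha, note = note)
    }
  }
  do.call(rbind, out)
}
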