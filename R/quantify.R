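#' Voxel-overlap agreement metrics
#'
#' Computes the Dice similarity coefficient
#' `DSC = 2|R ∩ T| / (|R| + |T|)`, intersection-over-union
#' `|R ∩ T| / |R ∪ T|`, pixel-wise precision `|R ∩ T| / |R|`, and pixel
#' accuracy (fraction of voxels where the masks agree). Two empty masks are
#' in perfect agreement: DSC, IoU and precision are all defined as 1.
#'
#' @param result predicted [mask_volume()] or binary array.
#' @param truth reference mask of the same shape.
#' @return A `segmentation_metrics` list: `dsc`, `iou`, `precision`,
#'   `pixel_accuracy`.
#' @export
segmentation_metrics <- function(result, truth) {
  r <- if (inherits(result, "mask_volume")) result$voxels else result
  t <- if (inherits(truth, "mask_volume")) truth$voxels else truth
  if (!identical(dim(r) %||% length(r), dim(t) %||% length(t))) {
    stop("result and truth shapes differ")
  }
  r <- r > 0; t <- t > 0
  inter <- sum(r & t)
  nr <- sum(r); nt <- sum(t)
  uni <- nr + nt - inter
  structure(list(
    dsc = if (nr + nt == 0) 1 else 2 * inter / (nr + nt),
    iou = if (uni == 0) 1 else inter / uni,
    precision = if (nr == 0) as.numeric(nt == 0) else inter / nr,
    pixel_accuracy = mean(r == t)),
    class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("<segmentation_metrics> DSC %.4f, IoU %.4f, precision %.4f, accuracy %.4f\n",
              x$dsc, x$iou, x$precision, x$pixel_accuracy))
  invisible(x)
}

#' Muscle volumetry and densitometry
#'
#' Per-slice muscle areas are the foreground pixel counts times the
#' in-plane pixel area `sx * sy` (mm^2); the volume is the summed area
#' across slices times the slice thickness, reported in cc
#' (`1 cc = 1000 mm^3`). Mean density is the mean HU of the CT voxels under
#' the mask (NA for an empty mask).
#'
#' @param ct a [ct_volume()].
#' @param mask an aligned [mask_volume()] (same shape and spacing).
#' @return A `muscle_quant` list: `volume_cc`, `mean_hu`, `voxel_count`,
#'   `slice_areas_mm2`.
#' @export
quantify_muscle <- function(ct, mask) {
  stopifnot(inherits(ct, "ct_volume"), inherits(mask, "mask_volume"))
  if (!identical(dim(ct$voxels), dim(mask$voxels))) stop("shape mismatch")
  if (max(abs(ct$spacing - mask$spacing)) > 1e-9) stop("spacing mismatch")
  sp <- ct$spacing
  nz <- dim(mask$voxels)[1]
  counts <- rowSums(matrix(mask$voxels, nrow = nz))
  areas <- counts * sp[1] * sp[2]
  vc <- sum(counts)
  structure(list(volume_cc = sum(areas) * sp[3] / 1000,
                 mean_hu = if (vc > 0) mean(ct$voxels[mask$voxels > 0])
                           else NA_real_,
                 voxel_count = vc, slice_areas_mm2 = areas),
            class = "muscle_quant")
}

#' @export
print.muscle_quant <- function(x, ...) {
  cat(sprintf("<muscle_quant> %.2f cc over %d voxels, mean density %s HU\n",
              x$volume_cc, x$voxel_count,
              ifelse(is.na(x$mean_hu), "NA", sprintf("%.1f", x$mean_hu))))
  invisible(x)
}

#' Compare a follow-up scan pair
#'
#' Given quantifications of two scans of the same subject, reports the
#' pre/post volume and density ratios (`100 * pre / post`, in percent) and
#' the absolute differences. The ratio orientation is fixed as pre over
#' post; pass arguments accordingly. The `outlier` flag is initialized
#' `FALSE` and set by [flag_outliers()].
#'
#' @param pre,post `muscle_quant` objects for the earlier and later scan.
#' @return A `followup_comparison` list: `ratio_volume_pct`,
#'   `ratio_density_pct`, `absdiff_volume_cc`, `absdiff_density_hu`,
#'   `outlier`.
#' @export
compare_followup <- function(pre, post) {
  stopifnot(inherits(pre, "muscle_quant"), inherits(post, "muscle_quant"))
  if (post$volume_cc <= 0) stop("post volume is zero; ratio undefined")
  structure(list(
    ratio_volume_pct = 100 * pre$volume_cc / post$volume_cc,
    ratio_density_pct = if (!is.na(pre$mean_hu) && !is.na(post$mean_hu) &&
                            abs(post$mean_hu) > 1e-12)
      100 * pre$mean_hu / post$mean_hu else NA_real_,
    absdiff_volume_cc = abs(pre$volume_cc - post$volume_cc),
    absdiff_density_hu = abs(pre$mean_hu - post$mean_hu),
    outlier = FALSE),
    class = "followup_comparison")
}

#' Flag outlier follow-up pairs by a k-SD rule
#'
#' A reproducible statistical surrogate for visual outlier screening: a
#' pair is flagged when its volume ratio deviates from the center of the
#' other pairs' ratios by more than `k` of their standard deviations
#' (leave-one-out, so one gross outlier cannot mask itself by inflating the
#' pooled spread). Flags are recomputed for the whole set on every call.
#'
#' @param pairs list of `followup_comparison` objects (>= 3).
#' @param k SD multiplier (default 2).
#' @return The list with the `outlier` flags set.
#' @export
flag_outliers <- function(pairs, k = 2) {
  stopifnot(k > 0)
  if (length(pairs) < 3) stop("need at least 3 pairs to flag outliers")
  ratios <- vapply(pairs, function(p) p$ratio_volume_pct, numeric(1))
  for (i in seq_along(pairs)) {
    rest <- ratios[-i]
    s <- stats::sd(rest)
    dev <- abs(ratios[i] - mean(rest))
    pairs[[i]]$outlier <- if (s < 1e-12) dev > 1e-12 * max(1, mean(rest))
                          else dev > k * s
  }
  pairs
}
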