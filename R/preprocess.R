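#' Resample a volume to isotropic voxels
#'
#' Interpolates a CT or mask volume onto a grid with equal spacing along all
#' three axes. Range detection operates on this grid so the anatomy is not
#' distorted by anisotropic slice thickness. The output length along each
#' axis is `max(1, round(n * s / target_mm))`, which preserves the physical
#' extent per axis to within one target voxel. CT volumes use linear
#' interpolation; masks must use nearest so they stay binary.
#'
#' @param vol a [ct_volume()] or [mask_volume()].
#' @param target_mm target isotropic spacing in mm (default 2).
#' @param order `"linear"` or `"nearest"`; masks force `"nearest"`.
#' @return An `iso_volume`: list with `voxels` (z, y, x), `iso_spacing`,
#'   `source_shape`, `source_spacing`, `kind`, `dose_tag`, `source_id`.
#' @export
resample_isotropic <- function(vol, target_mm = 2,
                               order = c("linear", "nearest")) {
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0) {
    stop("target_mm must be a single positive number")
  }
  order <- match.arg(order)
  is_mask <- inherits(vol, "mask_volume")
  if (is_mask) order <- "nearest"
  sp <- vol$spacing                       # (sx, sy, sz)
  ax_sp <- c(sp[3], sp[2], sp[1])         # spacing along (z, y, x)
  d <- dim(vol$voxels)
  newd <- pmax(1L, as.integer(round(d * ax_sp / target_mm)))
  out <- vol$voxels + 0.0
  for (ax in 1:3) {
    out <- interp_axis(out, ax, newd[ax], ax_sp[ax], target_mm, order)
  }
  if (is_mask) out <- array(as.integer(out > 0.5), dim = dim(out))
  structure(list(voxels = out, iso_spacing = target_mm, source_shape = d,
                 source_spacing = sp, kind = if (is_mask) "mask" else "ct",
                 dose_tag = vol$dose_tag %||% "unknown",
                 source_id = vol$source_id %||% ""),
            class = "iso_volume")
}

# Separable 1D interpolation along one axis of a 3D array, center-aligned:
# output index i' (0-based) samples input coordinate (i' + .5)*t/s - .5.
interp_axis <- function(a, axis, n_new, s, target, order) {
  d <- dim(a)
  n <- d[axis]
  if (n_new == n && abs(s - target) < 1e-12) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  pos <- (seq_len(n_new) - 0.5) * target / s - 0.5   # 0-based source coord
  pos <- pmin(pmax(pos, 0), n - 1)
  if (order == "nearest") {
    idx <- as.integer(round(pos)) + 1L
    res <- ap[idx, , , drop = FALSE]
  } else {
    i0 <- pmin(floor(pos), n - 1)
    w <- pos - i0
    lo <- as.integer(i0) + 1L
    hi <- pmin(lo + 1L, n)
    res <- ap[lo, , , drop = FALSE] * (1 - w) + ap[hi, , , drop = FALSE] * w
  }
  aperm(res, order(perm))
}

#' Map an isotropic-grid slice index back to an original axial slice
#'
#' Range detection runs on the isotropic grid but segmentation runs on the
#' original axial slices, so detected z indices must be mapped back. With
#' 1-based indices the original slice is `floor((z_iso - 1) * iso / sz) + 1`,
#' clamped to the valid slice range; the mapping is monotone non-decreasing.
#'
#' @param z_iso 1-based index (or vector of indices) on the isotropic z axis.
#' @param iso an `iso_volume` from [resample_isotropic()].
#' @return 1-based original axial slice index/indices.
#' @export
map_iso_z_to_original <- function(z_iso, iso) {
  nz_iso <- dim(iso$voxels)[1]
  if (any(z_iso < 1 | z_iso > nz_iso)) {
    stop("z_iso out of bounds [1, ", nz_iso, "]")
  }
  sz <- iso$source_spacing[3]
  s <- floor((z_iso - 1) * iso$iso_spacing / sz) + 1
  pmin(pmax(as.integer(s), 1L), iso$source_shape[1])
}

#' Window and normalize HU intensities to [0, 1]
#'
#' Maps `v` to `clip((v - lo) / (hi - lo), 0, 1)`. The default window
#' (-200, 300) HU brackets fat (~ -100 HU) through dense muscle, the range
#' that matters for muscle/soft-tissue contrast.
#'
#' @param img numeric array or matrix of HU values.
#' @param window length-2 `(lo, hi)` with `lo < hi`.
#' @return Same shape as `img`, values in `[0, 1]`.
#' @export
normalize_intensity <- function(img, window = c(-200, 300)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be (lo, hi) with lo < hi")
  }
  pmin(pmax((img - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Smooth a CT volume (denoising stand-in)
#'
#' Generic per-slice filters offered as an optional noise-reduction hook at
#' the head of the pipeline. `"gaussian"` applies an isotropic Gaussian blur
#' with `strength` as sigma in pixels; `"median"` a median filter with
#' `strength` as window radius; `"none"` returns the input untouched.
#'
#' @param vol a [ct_volume()].
#' @param method `"none"`, `"gaussian"`, or `"median"`.
#' @param strength positive filter strength.
#' @return A [ct_volume()] with identical shape, spacing and metadata.
#' @export
denoise <- function(vol, method = c("none", "gaussian", "median"),
                    strength = 1) {
  method <- match.arg(method)
  if (method == "none") return(vol)
  stopifnot(strength > 0)
  v <- vol$voxels
  nz <- dim(v)[1]
  out <- v
  if (method == "gaussian") {
    for (z in seq_len(nz)) {
      out[z, , ] <- EBImage::gblur(v[z, , ], sigma = strength)
    }
  } else {
    rng <- range(v)
    den <- max(rng[2] - rng[1], 1e-9)
    for (z in seq_len(nz)) {
      sl <- (v[z, , ] - rng[1]) / den
      sl <- EBImage::medianFilter(sl, size = max(1L, as.integer(strength)))
      out[z, , ] <- sl * den + rng[1]
    }
  }
  ct_volume(out, spacing = vol$spacing, origin = vol$origin,
            dose_tag = vol$dose_tag, source_id = vol$source_id)
}
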