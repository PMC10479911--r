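#' CT and mask volume containers
#'
#' A `ct_volume` holds a 3D grid of Hounsfield units indexed `(z, y, x)` =
#' (axial slice, anteroposterior row, left-right column), together with the
#' in-plane and axial voxel spacing in mm. A `mask_volume` is the binary
#' counterpart, aligned voxel-for-voxel with its CT.
#'
#' @param voxels 3D numeric array, `(z, y, x)` order.
#' @param spacing numeric length-3, `(sx, sy, sz)` mm, all strictly positive.
#'   `sx`/`sy` are the in-plane spacings along the x/y axes, `sz` the slice
#'   thickness.
#' @param origin physical position of the first voxel in mm.
#' @param dose_tag one of `"low"`, `"normal"`, `"unknown"`. Low-dose scans
#'   carry substantially more image noise.
#' @param source_id free-text identifier.
#' @return An object of class `ct_volume` (or `mask_volume`).
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      dose_tag = "unknown", source_id = "") {
  stopifnot(length(dim(voxels)) == 3, all(dim(voxels) > 0))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three strictly positive mm values (sx, sy, sz)")
  }
  dose_tag <- match.arg(dose_tag, c("low", "normal", "unknown"))
  voxels[] <- pmin(pmax(voxels, -1024), 3071)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), dose_tag = dose_tag,
                 source_id = source_id),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
mask_volume <- function(voxels, spacing, origin = c(0, 0, 0), source_id = "") {
  stopifnot(length(dim(voxels)) == 3, all(dim(voxels) > 0))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three strictly positive mm values (sx, sy, sz)")
  }
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1))) stop("mask voxels must be binary (0/1)")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), source_id = source_id),
            class = "mask_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d (z,y,x), spacing %.2f/%.2f/%.2f mm, dose %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$dose_tag))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume> %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Read a CT or mask volume from NIfTI
#'
#' Loads a `.nii`/`.nii.gz` file, takes the voxel spacing from the header,
#' and permutes the on-disk `(x, y, z)` axes to the package-wide `(z, y, x)`
#' convention, so iterating dimension 1 walks axial slices. Masks are
#' binarized (`> 0` becomes 1) and validated to carry integer-valued voxels.
#'
#' @param path path to a NIfTI file.
#' @param kind `"ct"` or `"mask"`.
#' @param dose_tag,source_id metadata attached to the returned volume.
#' @return A [ct_volume()] or [mask_volume()].
#' @export
load_volume <- function(path, kind = c("ct", "mask"), dose_tag = "unknown",
                        source_id = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("expected a 3D image, got ",
                                  length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]   # (sx, sy, sz)
  vox <- aperm(arr, c(3, 2, 1))    # (x, y, z) -> (z, y, x)
  if (kind == "ct") {
    ct_volume(vox, spacing = sp, dose_tag = dose_tag, source_id = source_id)
  } else {
    if (max(abs(vox - round(vox))) > 1e-6) {
      stop("mask volume has non-integer voxel values")
    }
    mask_volume((round(vox) > 0) + 0L, spacing = sp, source_id = source_id)
  }
}

#' Write a CT or mask volume to NIfTI
#'
#' CT volumes are stored as float32, masks as unsigned 8-bit, both with the
#' spacing recorded in the header. A save/load round trip reproduces mask
#' voxels exactly and CT voxels to float32 precision.
#'
#' @param vol a [ct_volume()] or [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume") || inherits(vol, "mask_volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  arr <- aperm(vol$voxels, c(3, 2, 1))  # back to on-disk (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  dt <- if (inherits(vol, "mask_volume")) "uint8" else "float"
  ok <- try(RNifti::writeNifti(img, path, datatype = dt), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path)) {
    stop("could not write NIfTI to ", path)
  }
  invisible(path)
}
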