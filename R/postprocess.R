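#' Post-processing configuration
#'
#' Bundles the mask-cleanup settings applied after slice segmentation:
#' small-component removal per slice, morphological closing and hole
#' filling, 3D connectivity filtering down to the largest components
#' (default 2, the left and right pectoralis), and bridging of short
#' empty-slice gaps by shape-based interpolation.
#'
#' @param min_component_px 2D area cutoff in pixels (default 50).
#' @param closing_radius disc radius in px for morphological closing
#'   (default 2; 0 disables closing).
#' @param fill_holes fill enclosed 2D holes (default TRUE).
#' @param connectivity_3d 6 or 26 (default 26).
#' @param keep_components number of 3D components kept (default 2).
#' @param max_gap largest empty-slice run bridged by interpolation
#'   (default 1).
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(min_component_px = 50, closing_radius = 2,
                               fill_holes = TRUE, connectivity_3d = 26,
                               keep_components = 2, max_gap = 1) {
  stopifnot(min_component_px >= 0, closing_radius >= 0,
            connectivity_3d %in% c(6, 26), keep_components >= 0, max_gap >= 0)
  structure(list(min_component_px = min_component_px,
                 closing_radius = closing_radius,
                 fill_holes = isTRUE(fill_holes),
                 connectivity_3d = as.integer(connectivity_3d),
                 keep_components = as.integer(keep_components),
                 max_gap = as.integer(max_gap)),
            class = "postprocess_config")
}

#' Remove small 2D components
#'
#' Deletes every 8-connected component of a binary slice whose pixel area is
#' below `min_px`; larger components are untouched. Anti-extensive and
#' idempotent.
#'
#' @param mask binary 2D matrix.
#' @param min_px area cutoff.
#' @return Binary matrix of the same shape.
#' @export
filter_components_2d <- function(mask, min_px = 50) {
  m <- (mask > 0) + 0L
  if (!any(m > 0) || min_px <= 1) return(matrix(as.integer(m), nrow(mask)))
  lab <- cpp_label_components(as.integer(m), 1L, nrow(m), ncol(m), 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab %in% keep & lab > 0), nrow(m))
}

#' Morphological smoothing and hole filling of a 2D mask
#'
#' Morphological closing (dilation then erosion) with a disc structuring
#' element, followed by filling of enclosed holes. Closing a convex solid is
#' the identity; the operation only adds pixels in concavities and holes.
#'
#' @param mask binary 2D matrix.
#' @param radius disc radius in px (0 skips closing).
#' @param fill_holes fill enclosed background regions.
#' @return Binary matrix of the same shape.
#' @export
morphological_refine <- function(mask, radius = 2, fill_holes = TRUE) {
  m <- (mask > 0) + 0
  if (radius > 0 && any(m > 0)) {
    kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- EBImage::closing(m, kern)
  }
  if (fill_holes && any(m > 0)) m <- EBImage::fillHull(m)
  matrix(as.integer(m > 0), nrow(mask))
}

#' Keep the largest 3D components of a mask stack
#'
#' Labels the binary stack with the chosen 3D connectivity and keeps only
#' the `keep_components` largest components by voxel count (ties broken by
#' earliest raster-scan position). This removes spurious blobs that share
#' muscle-like intensity but are not connected to the bilateral pectoralis.
#'
#' @param stack a [mask_volume()] or binary 3D array, `(z, y, x)`.
#' @param connectivity 6 or 26.
#' @param keep_components number of components retained.
#' @return Same type as the input.
#' @export
connectivity_filter_3d <- function(stack, connectivity = 26,
                                   keep_components = 2) {
  is_vol <- inherits(stack, "mask_volume")
  v <- if (is_vol) stack$voxels else (stack > 0) + 0L
  d <- dim(v)
  out <- v
  if (any(v > 0) && keep_components >= 0) {
    lab <- cpp_label_components(as.integer(v), d[1], d[2], d[3],
                                as.integer(connectivity))
    sizes <- tabulate(lab)
    if (length(sizes) > keep_components) {
      first_seen <- match(seq_along(sizes), as.vector(lab))
      ord <- order(-sizes, first_seen)
      keep <- ord[seq_len(min(keep_components, length(ord)))]
      out <- array(as.integer(lab %in% keep & lab > 0), dim = d)
    }
  }
  if (is_vol) mask_volume(out, stack$spacing, stack$origin, stack$source_id)
  else out
}

#' Bridge short empty-slice gaps by shape-based interpolation
#'
#' For every run of empty axial slices of length at most `max_gap` flanked
#' by nonempty slices, fills each gap slice with the average of the two
#' flanking signed Euclidean distance maps (positive inside, negative
#' outside), thresholded at zero. Identical flanks reproduce the flank
#' shape; differing flanks yield a smooth transitional contour. Longer gaps
#' and all originally nonempty slices are untouched.
#'
#' @param stack a [mask_volume()] or binary 3D array.
#' @param max_gap largest gap bridged (default 1).
#' @return Same type as the input.
#' @export
interpolate_between_slices <- function(stack, max_gap = 1) {
  is_vol <- inherits(stack, "mask_volume")
  v <- if (is_vol) stack$voxels else (stack > 0) + 0L
  d <- dim(v)
  nz <- d[1]
  nonempty <- rowSums(matrix(v, nrow = nz)) > 0
  out <- v
  if (max_gap >= 1 && any(nonempty)) {
    r <- rle(nonempty)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i] || r$lengths[i] > max_gap) next
      if (i == 1 || i == length(r$values)) next   # not flanked on both sides
      a <- out[starts[i] - 1, , ]
      b <- out[ends[i] + 1, , ]
      sda <- signed_distance(a)
      sdb <- signed_distance(b)
      gap <- r$lengths[i]
      for (j in seq_len(gap)) {
        w <- j / (gap + 1)
        out[starts[i] + j - 1, , ] <-
          as.integer(((1 - w) * sda + w * sdb) > 0)
      }
    }
  }
  if (is_vol) mask_volume(out, stack$spacing, stack$origin, stack$source_id)
  else out
}

# Signed Euclidean distance map of a binary slice: positive inside the
# foreground, negative outside; never exactly zero for a binary input.
signed_distance <- function(m) {
  m <- (m > 0) + 0
  EBImage::distmap(m) - EBImage::distmap(1 - m)
}

#' Full per-volume post-processing chain
#'
#' Applies, in order: per-slice small-component removal, per-slice
#' morphological refinement, 3D connectivity filtering, and inter-slice gap
#' interpolation, as configured by [postprocess_config()].
#'
#' @param mask a [mask_volume()].
#' @param cfg a [postprocess_config()].
#' @return A cleaned [mask_volume()].
#' @export
postprocess_mask <- function(mask, cfg = postprocess_config()) {
  stopifnot(inherits(mask, "mask_volume"), inherits(cfg, "postprocess_config"))
  v <- mask$voxels
  nz <- dim(v)[1]
  for (z in seq_len(nz)) {
    sl <- v[z, , ]
    if (!any(sl > 0)) next
    sl <- filter_components_2d(sl, cfg$min_component_px)
    sl <- morphological_refine(sl, cfg$closing_radius, cfg$fill_holes)
    v[z, , ] <- sl
  }
  out <- mask_volume(v, mask$spacing, mask$origin, mask$source_id)
  out <- connectivity_filter_3d(out, cfg$connectivity_3d, cfg$keep_components)
  interpolate_between_slices(out, cfg$max_gap)
}
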