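#' Fused multichannel coronal image
#'
#' Builds the 3-channel coronal image that feeds the range-detection model.
#' Channel k is the coronal plane of the isotropic volume at anteroposterior
#' row `round(f_k * (Ny - 1)) + 1`, window-normalized to `[0, 1]`. The
#' default fractions 3/8, 4/8, 5/8 straddle the mid-coronal plane, where the
#' pectoralis lies, and give three complementary views of the chest wall in
#' one stacked image.
#'
#' @param iso an `iso_volume` from [resample_isotropic()].
#' @param fractions three strictly increasing anteroposterior fractions in
#'   (0, 1).
#' @param window HU window passed to [normalize_intensity()].
#' @return A `fused_coronal` object: `channels` array of dim
#'   `(z, x, 3)`, plus `fractions` and `source_id`.
#' @export
extract_fused_coronal <- function(iso, fractions = c(3, 4, 5) / 8,
                                  window = c(-200, 300)) {
  stopifnot(inherits(iso, "iso_volume"))
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1)) {
    stop("fractions must be three values strictly inside (0, 1)")
  }
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  d <- dim(iso$voxels)
  rows <- as.integer(round(fractions * (d[2] - 1))) + 1L
  ch <- array(0, dim = c(d[1], d[3], 3L))
  for (k in 1:3) {
    ch[, , k] <- normalize_intensity(iso$voxels[, rows[k], ], window)
  }
  structure(list(channels = ch, fractions = fractions, rows = rows,
                 source_id = iso$source_id),
            class = "fused_coronal")
}

#' Jittered fusion-position triples for augmentation and multi-view voting
#'
#' The acquisition position of the coronal planes is varied rigidly: each
#' returned triple is `base + u` for one shared offset
#' `u ~ Uniform(-max_offset, max_offset)`, so the three channels always move
#' together. The first triple is always `base` itself. Used both to augment
#' the range-model training set (10 views per case) and at prediction time
#' (5 views whose predicted ranges are median-aggregated).
#'
#' @param base three base fractions in (0, 1).
#' @param n number of triples (>= 1).
#' @param max_offset maximum absolute shared offset; `base` plus/minus
#'   `max_offset` must stay inside (0, 1).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return List of `n` numeric length-3 vectors.
#' @export
sample_fusion_positions <- function(base = c(3, 4, 5) / 8, n = 5,
                                    max_offset = 1 / 16, seed = 1) {
  stopifnot(n >= 1, max_offset >= 0)
  if (min(base) - max_offset <= 0 || max(base) + max_offset >= 1) {
    stop("offset range pushes fractions outside (0, 1)")
  }
  out <- vector("list", n)
  out[[1]] <- base
  if (n > 1) {
    u <- with_seed(seed, stats::runif(n - 1, -max_offset, max_offset))
    for (i in seq_len(n - 1)) out[[i + 1]] <- base + u[i]
  }
  out
}

#' Per-slice presence labels from a mask
#'
#' Projects a binary isotropic mask onto the z axis: bin z is 1 iff any mask
#' voxel exists in axial slice z. These vectors are the annotation targets
#' for the range-detection model.
#'
#' @param mask_iso an `iso_volume` of kind `"mask"`, or a `mask_volume`.
#' @return Integer 0/1 vector of length equal to the z extent.
#' @export
derive_range_label <- function(mask_iso) {
  v <- mask_iso$voxels
  if (!all(unique(as.vector(v)) %in% c(0, 1))) {
    stop("mask must be binary")
  }
  nz <- dim(v)[1]
  as.integer(rowSums(matrix(v, nrow = nz)) > 0)
}

# Evaluate the R expression with a temporary RNG state; restores (or clears)
# the caller's .Random.seed so seeded helpers do not perturb outer streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
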