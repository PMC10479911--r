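#' Synthetic labeled chest-CT phantom specification
#'
#' Parameterizes a synthetic axial chest-CT volume with known ground truth:
#' an elliptical soft-tissue body with a subcutaneous fat rim, two lung
#' fields, spine and rib bone, and paired anterior muscle slabs with
#' crescent cross-sections that exist only within a limited vertical range.
#' The crescent geometry is deliberately simple rather than anatomically
#' faithful: the left/right components are separable by connectivity and
#' the true cross-section area is computable, which is what training and
#' validation need. Additive Gaussian noise emulates the dose class: 10 HU
#' for normal-dose, 25 HU for low-dose scans.
#'
#' @param shape `(Nz, Ny, Nx)` voxel counts (default `c(64, 96, 96)`).
#' @param spacing `(sx, sy, sz)` mm (default `c(1.5, 1.5, 3)`, i.e. 3 mm
#'   slices).
#' @param hu_means named tissue HU means
#'   (air -1000, lung -800, fat -100, soft 40, muscle 55, bone 700).
#' @param hu_sds per-tissue HU texture SDs (default all 0, so the pre-noise
#'   volume is piecewise constant and the label is exact).
#' @param muscle_z_fraction `(f_lo, f_hi)` fraction of the z extent carrying
#'   muscle, `0 <= f_lo < f_hi <= 1`.
#' @param muscle_thickness_px crescent thickness in pixels (default 10,
#'   about 15 mm at 1.5 mm pixels).
#' @param bilateral both crescents (default TRUE); FALSE keeps only the
#'   right one.
#' @param dose `"normal"` or `"low"`; sets the default `noise_sd`.
#' @param noise_sd additive Gaussian noise SD in HU; `NULL` uses the dose
#'   default (10 normal, 25 low).
#' @param distractor_components number of small muscle-HU blobs disjoint
#'   from the true mask (default 0).
#' @param mammary_blob add a soft-tissue blob abutting the muscle
#'   anteriorly, a qualitative leakage fixture (default FALSE).
#' @param seed integer seed; generation is bit-deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 96, 96), spacing = c(1.5, 1.5, 3),
                         hu_means = c(air = -1000, lung = -800, fat = -100,
                                      soft = 40, muscle = 55, bone = 700),
                         hu_sds = c(air = 0, lung = 0, fat = 0, soft = 0,
                                    muscle = 0, bone = 0),
                         muscle_z_fraction = c(0.25, 0.65),
                         muscle_thickness_px = 10, bilateral = TRUE,
                         dose = c("normal", "low"), noise_sd = NULL,
                         distractor_components = 0, mammary_blob = FALSE,
                         seed = 1) {
  dose <- match.arg(dose)
  if (is.null(noise_sd)) noise_sd <- if (dose == "low") 25 else 10
  f <- muscle_z_fraction
  stopifnot(length(shape) == 3, all(shape > 0), all(spacing > 0),
            length(f) == 2, f[1] >= 0, f[1] < f[2], f[2] <= 1,
            muscle_thickness_px > 0, noise_sd >= 0,
            distractor_components >= 0)
  need <- c("air", "lung", "fat", "soft", "muscle", "bone")
  stopifnot(all(need %in% names(hu_means)), all(need %in% names(hu_sds)))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 hu_means = hu_means, hu_sds = hu_sds,
                 muscle_z_fraction = f,
                 muscle_thickness_px = muscle_thickness_px,
                 bilateral = isTRUE(bilateral), dose = dose,
                 noise_sd = noise_sd,
                 distractor_components = as.integer(distractor_components),
                 mammary_blob = isTRUE(mammary_blob),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# In-plane geometry shared by the CT map and the true mask. All regions are
# indicator matrices over the (y, x) cross-section; y = 1 is anterior.
phantom_geometry <- function(spec, supersample = 1L) {
  ny <- spec$shape[2] * supersample
  nx <- spec$shape[3] * supersample
  yy <- matrix((seq_len(ny) - 0.5) / supersample + 0.5, ny, nx)
  xx <- matrix((seq_len(nx) - 0.5) / supersample + 0.5, ny, nx, byrow = TRUE)
  Ny <- spec$shape[2]; Nx <- spec$shape[3]
  cy <- (Ny + 1) / 2; cx <- (Nx + 1) / 2
  ay <- 0.40 * Ny; ax <- 0.44 * Nx
  ell <- function(ecy, ecx, ry, rx) {
    ((yy - ecy) / ry)^2 + ((xx - ecx) / rx)^2 <= 1
  }
  body <- ell(cy, cx, ay, ax)
  soft <- ell(cy, cx, 0.88 * ay, 0.88 * ax)
  lungL <- ell(cy + 0.05 * Ny, cx - 0.22 * Nx, 0.26 * Ny, 0.16 * Nx)
  lungR <- ell(cy + 0.05 * Ny, cx + 0.22 * Nx, 0.26 * Ny, 0.16 * Nx)
  spine <- ell(cy + 0.30 * Ny, cx, 0.06 * Ny, 0.05 * Nx)
  ribL <- ell(cy + 0.18 * Ny, cx - 0.36 * Nx, 0.04 * Ny, 0.035 * Nx)
  ribR <- ell(cy + 0.18 * Ny, cx + 0.36 * Nx, 0.04 * Ny, 0.035 * Nx)
  my <- 0.80 * ay; mx <- 0.84 * ax
  u <- sqrt(((yy - cy) / my)^2 + ((xx - cx) / mx)^2)
  t_norm <- spec$muscle_thickness_px / ((my + mx) / 2)
  anterior <- (cy - yy) / my > 0.35 * u
  gap <- abs(xx - cx) > 3
  band <- u <= 1 & u > 1 - t_norm & anterior & gap
  if (!spec$bilateral) band <- band & (xx > cx)
  list(body = body, soft = soft, lung = lungL | lungR,
       bone = spine | ribL | ribR, muscle = band,
       center = c(cy, cx), muscle_axes = c(my, mx))
}

#' Generate a labeled synthetic chest-CT phantom
#'
#' Rasterizes the geometry of a [phantom_spec()] into a CT volume and its
#' exact muscle mask. The mask marks the muscle voxels of the pre-noise
#' volume; distractor blobs share the muscle HU but are never part of the
#' mask. Identical specs (including seed) produce bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return `list(ct = ct_volume, mask = mask_volume, spec = spec)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  g <- phantom_geometry(spec)
  hu <- spec$hu_means
  base <- matrix(hu["air"], d[2], d[3])
  base[g$body] <- hu["fat"]
  base[g$soft] <- hu["soft"]
  base[g$lung] <- hu["lung"]
  base[g$bone] <- hu["bone"]

  z_lo <- round(spec$muscle_z_fraction[1] * d[1]) + 1L
  z_hi <- round(spec$muscle_z_fraction[2] * d[1])
  z_range <- if (z_hi >= z_lo) z_lo:z_hi else integer(0)

  ct <- aperm(array(base, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  mask <- array(0L, dim = d)
  slab <- matrix(base, d[2], d[3])
  slab[g$muscle] <- hu["muscle"]
  for (z in z_range) {
    ct[z, , ] <- slab
    mask[z, , ] <- g$muscle
  }

  with_seed(spec$seed, {
    if (spec$mammary_blob) {
      cy <- g$center[1]; cx <- g$center[2]
      by_ <- g$muscle_axes[1]
      yy <- matrix(seq_len(d[2]), d[2], d[3])
      xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
      blob <- ((yy - (cy - by_ - 2)) / 4)^2 +
        ((xx - (cx + 0.35 * d[3] / 2)) / 6)^2 <= 1
      blob <- blob & !g$muscle
      mid <- z_range[max(1, length(z_range) %/% 2)]
      zb <- max(1, mid - 2):min(d[1], mid + 2)
      for (z in zb) {
        sl <- ct[z, , ]
        sl[blob & sl > -500] <- hu["soft"] - 5
        ct[z, , ] <- sl
      }
    }
    if (spec$distractor_components > 0) {
      cy <- g$center[1]; cx <- g$center[2]
      for (i in seq_len(spec$distractor_components)) {
        bcy <- cy + stats::runif(1, 0.10, 0.24) * d[2]
        bcx <- cx + sample(c(-1, 1), 1) * stats::runif(1, 0.04, 0.28) * d[3]
        ry <- stats::runif(1, 1.5, 3); rx <- stats::runif(1, 1.5, 3)
        zc <- sample(seq_len(d[1]), 1)
        rz <- sample(1:2, 1)
        yy <- matrix(seq_len(d[2]), d[2], d[3])
        xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
        blob2d <- ((yy - bcy) / ry)^2 + ((xx - bcx) / rx)^2 <= 1
        blob2d <- blob2d & g$soft & !g$lung & !g$bone & !g$muscle
        for (z in max(1, zc - rz):min(d[1], zc + rz)) {
          sl <- ct[z, , ]
          sl[blob2d] <- hu["muscle"]
          ct[z, , ] <- sl
        }
      }
    }
    if (any(spec$hu_sds > 0)) {
      # Per-tissue texture: a (y, x) SD map mirroring the tissue map,
      # muscle SD only on muscle-bearing slices.
      sdmap <- matrix(spec$hu_sds["air"], d[2], d[3])
      sdmap[g$body] <- spec$hu_sds["fat"]
      sdmap[g$soft] <- spec$hu_sds["soft"]
      sdmap[g$lung] <- spec$hu_sds["lung"]
      sdmap[g$bone] <- spec$hu_sds["bone"]
      sdmap_m <- sdmap
      sdmap_m[g$muscle] <- spec$hu_sds["muscle"]
      for (z in seq_len(d[1])) {
        sm <- if (z %in% z_range) sdmap_m else sdmap
        ct[z, , ] <- ct[z, , ] + stats::rnorm(length(sm), 0, 1) * sm
      }
    }
    if (spec$noise_sd > 0) {
      ct <- ct + array(stats::rnorm(length(ct), 0, spec$noise_sd), dim = d)
    }
  })
  list(ct = ct_volume(ct, spacing = spec$spacing, dose_tag = spec$dose,
                      source_id = sprintf("phantom_seed%d", spec$seed)),
       mask = mask_volume(mask, spacing = spec$spacing,
                          source_id = sprintf("phantom_seed%d", spec$seed)),
       spec = spec)
}

#' Reference muscle volume of a phantom spec
#'
#' Computes the expected true muscle volume in cc from the crescent
#' construction itself, by super-sampled rasterization of the cross-section
#' (independent of the voxel-grid mask), times the number of muscle-bearing
#' slices and the slice thickness.
#'
#' @param spec a [phantom_spec()].
#' @param supersample linear super-sampling factor (default 4).
#' @return Volume in cc.
#' @export
phantom_expected_volume <- function(spec, supersample = 4L) {
  g <- phantom_geometry(spec, supersample = as.integer(supersample))
  area_mm2 <- sum(g$muscle) / supersample^2 * spec$spacing[1] * spec$spacing[2]
  d <- spec$shape
  z_lo <- round(spec$muscle_z_fraction[1] * d[1]) + 1L
  z_hi <- round(spec$muscle_z_fraction[2] * d[1])
  n_slices <- max(0L, z_hi - z_lo + 1L)
  area_mm2 * n_slices * spec$spacing[3] / 1000
}

#' Small physiological change between two scans of one subject
#'
#' @param volume_scale multiplicative factor on the muscle cross-section
#'   area (> 0).
#' @param shift_px rigid in-plane `(dy, dx)` shift in pixels.
#' @param noise_delta additive increase of the noise SD in HU.
#' @param seed seed for the second scan's noise.
#' @return A `followup_perturbation` list.
#' @export
followup_perturbation <- function(volume_scale = 1, shift_px = c(0, 0),
                                  noise_delta = 0, seed = 2) {
  stopifnot(volume_scale > 0, length(shift_px) %in% c(1, 2))
  if (length(shift_px) == 1) shift_px <- c(shift_px, shift_px)
  structure(list(volume_scale = volume_scale, shift_px = shift_px,
                 noise_delta = noise_delta, seed = as.integer(seed)),
            class = "followup_perturbation")
}

#' Generate a follow-up phantom pair
#'
#' The first scan realizes `spec`; the second differs by a scaled muscle
#' cross-section (thickness scaling, so the true mask volume scales by
#' approximately `volume_scale`), a rigid in-plane shift, and extra noise.
#'
#' @param spec a [phantom_spec()] for the baseline scan.
#' @param perturb a [followup_perturbation()].
#' @return `list(pre =, post =)`, each a [generate_phantom()] result.
#' @export
generate_followup_pair <- function(spec, perturb) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(perturb, "followup_perturbation"))
  pre <- generate_phantom(spec)
  spec2 <- spec
  spec2$muscle_thickness_px <- spec$muscle_thickness_px * perturb$volume_scale
  spec2$noise_sd <- spec$noise_sd + perturb$noise_delta
  spec2$seed <- perturb$seed
  post <- generate_phantom(spec2)
  sh <- round(perturb$shift_px)
  if (any(sh != 0)) {
    post$ct$voxels <- shift_inplane(post$ct$voxels, sh,
                                    fill = spec$hu_means["air"])
    post$mask$voxels <- array(as.integer(
      shift_inplane(post$mask$voxels, sh, fill = 0L)),
      dim = dim(post$mask$voxels))
  }
  list(pre = pre, post = post)
}

# Rigid in-plane (y, x) shift of a (z, y, x) array with constant fill.
shift_inplane <- function(v, sh, fill = 0) {
  d <- dim(v)
  out <- array(fill, dim = d)
  ys <- seq_len(d[2]) - sh[1]
  xs <- seq_len(d[3]) - sh[2]
  oky <- ys >= 1 & ys <= d[2]
  okx <- xs >= 1 & xs <= d[3]
  out[, oky, okx] <- v[, ys[oky], xs[okx]]
  out
}

#' Generate a randomized phantom training set
#'
#' Samples `n` phantom specs uniformly within the given per-field ranges and
#' rasterizes each. Dose tags are assigned so that exactly
#' `round(low_dose_prop * n)` phantoms are low-dose (the mixed-dose makeup
#' of a screening cohort), at seeded random positions.
#'
#' @param n number of phantoms.
#' @param spec_ranges list of sampling ranges: `f_lo` (range of the lower
#'   muscle fraction), `span` (range of `f_hi - f_lo`), `thickness_px`,
#'   `distractors` (integer candidates), `low_dose_prop` (scalar).
#' @param seed integer seed; the set is reproducible.
#' @param shape,spacing passed to every [phantom_spec()].
#' @return List of `n` [generate_phantom()] results.
#' @export
generate_training_set <- function(n,
                                  spec_ranges = list(
                                    f_lo = c(0.15, 0.35),
                                    span = c(0.25, 0.45),
                                    thickness_px = c(8, 12),
                                    distractors = 0:2,
                                    low_dose_prop = 0.7),
                                  seed = 1,
                                  shape = c(64, 96, 96),
                                  spacing = c(1.5, 1.5, 3)) {
  stopifnot(n >= 1)
  r <- spec_ranges
  for (nm in c("f_lo", "span", "thickness_px")) {
    if (length(r[[nm]]) != 2 || r[[nm]][2] < r[[nm]][1]) {
      stop("invalid range for ", nm)
    }
  }
  specs <- with_seed(seed, {
    n_low <- round(r$low_dose_prop * n)
    low_idx <- sample.int(n, n_low)
    lapply(seq_len(n), function(i) {
      f_lo <- stats::runif(1, r$f_lo[1], r$f_lo[2])
      span <- stats::runif(1, r$span[1], r$span[2])
      phantom_spec(shape = shape, spacing = spacing,
                   muscle_z_fraction = c(f_lo, min(f_lo + span, 0.95)),
                   muscle_thickness_px = stats::runif(1, r$thickness_px[1],
                                                      r$thickness_px[2]),
                   dose = if (i %in% low_idx) "low" else "normal",
                   distractor_components = if (length(r$distractors) == 1)
                     r$distractors else sample(r$distractors, 1),
                   seed = sample.int(2^30, 1))
    })
  })
  lapply(specs, generate_phantom)
}
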