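test_that("isotropic resampling follows the extent rule n' = round(n*s/t)", {
  set.seed(2)
  vox <- array(rnorm(5 * 10 * 10, 0, 100), dim = c(5, 10, 10))
  ct <- ct_volume(vox, spacing = c(1, 1, 3))   # (sx, sy, sz)
  iso <- resample_isotropic(ct, 1)
  expect_equal(dim(iso$voxels), c(15, 10, 10))
  expect_equal(iso$iso_spacing, 1)
  # linear interpolation never exceeds the input range
  expect_gte(min(iso$voxels), min(vox))
  expect_lte(max(iso$voxels), max(vox))
})

test_that("nearest-neighbour z resampling matches a manual index oracle", {
  set.seed(3)
  vox <- array(rnorm(6 * 4 * 4), dim = c(6, 4, 4))
  ct <- ct_volume(vox, spacing = c(1, 1, 2))
  iso <- resample_isotropic(ct, 1, "nearest")
  expect_equal(dim(iso$voxels), c(12, 4, 4))
  # oracle: output slice i' samples input slice round((i'-0.5)*t/s - 0.5)+1
  for (zp in c(1, 5, 12)) {
    src <- round((zp - 0.5) * 1 / 2 - 0.5) + 1
    src <- min(max(src, 1), 6)
    expect_equal(iso$voxels[zp, , ], vox[src, , ])
  }
})

test_that("constant and already-isotropic volumes pass through unchanged", {
  ct <- ct_volume(array(42, dim = c(4, 6, 6)), spacing = c(2, 2, 2))
  iso_same <- resample_isotropic(ct, 2)
  expect_identical(iso_same$voxels, ct$voxels)
  iso_fine <- resample_isotropic(ct, 1)
  expect_true(all(iso_fine$voxels == 42))
  expect_error(resample_isotropic(ct, -1), "positive")
})

test_that("masks stay binary under resampling", {
  set.seed(4)
  mk <- mask_volume(array(as.integer(runif(5 * 8 * 8) > 0.5), c(5, 8, 8)),
                    spacing = c(1, 1, 3))
  iso <- resample_isotropic(mk, 2)
  expect_true(all(iso$voxels %in% c(0L, 1L)))
})

test_that("iso-to-original slice mapping is correct, clamped and monotone", {
  ct <- ct_volume(array(0, dim = c(20, 6, 6)), spacing = c(1, 1, 3))
  iso <- resample_isotropic(ct, 1)
  # 0-based z_iso = 30 with 1 mm iso and 3 mm slices -> 0-based slice 10
  expect_equal(map_iso_z_to_original(31, iso), 11L)
  expect_equal(map_iso_z_to_original(1, iso), 1L)
  nz_iso <- dim(iso$voxels)[1]
  expect_lte(map_iso_z_to_original(nz_iso, iso), 20L)
  m <- map_iso_z_to_original(seq_len(nz_iso), iso)
  expect_true(all(diff(m) >= 0))
  expect_error(map_iso_z_to_original(0, iso), "bounds")
  expect_error(map_iso_z_to_original(nz_iso + 1, iso), "bounds")
})

test_that("intensity normalization maps the window to [0, 1] and clips", {
  expect_equal(normalize_intensity(-200), 0)
  expect_equal(normalize_intensity(300), 1)
  expect_equal(normalize_intensity(50, c(-200, 300)), 0.5)
  expect_equal(normalize_intensity(-1000), 0)
  expect_equal(normalize_intensity(2000), 1)
  expect_error(normalize_intensity(0, c(10, 10)), "lo < hi")
  # monotone; idempotent on already-normalized input with window (0, 1)
  x <- seq(-400, 500, by = 7)
  y <- normalize_intensity(x)
  expect_true(all(diff(y) >= 0))
  expect_equal(normalize_intensity(y, c(0, 1)), y)
})

test_that("denoising reduces variance of pure noise and keeps constants", {
  set.seed(5)
  noisy <- ct_volume(array(rnorm(4 * 32 * 32, 0, 25), c(4, 32, 32)),
                     spacing = c(1, 1, 3))
  out <- denoise(noisy, "gaussian", 1.5)
  expect_identical(dim(out$voxels), dim(noisy$voxels))
  expect_lt(var(as.vector(out$voxels)), var(as.vector(noisy$voxels)))
  flat <- ct_volume(array(40, c(3, 16, 16)), spacing = c(1, 1, 3))
  expect_equal(as.vector(denoise(flat, "gaussian", 1)$voxels),
               rep(40, 3 * 16 * 16), tolerance = 1e-6)
  expect_identical(denoise(noisy, "none"), noisy)
  med <- denoise(noisy, "median", 2)
  expect_lt(var(as.vector(med$voxels)), var(as.vector(noisy$voxels)))
  expect_error(denoise(noisy, "wavelet"), "arg")
})
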