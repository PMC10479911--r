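test_that("phantom generation is bit-deterministic and labeled correctly", {
  spec <- tiny_phantom_spec(seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  # the muscle occupies exactly [round(f_lo*Nz), round(f_hi*Nz)) (0-based)
  nz <- spec$shape[1]
  lab <- vapply(seq_len(nz),
                function(z) as.integer(any(a$mask$voxels[z, , ] > 0)),
                integer(1))
  z_lo <- round(spec$muscle_z_fraction[1] * nz) + 1
  z_hi <- round(spec$muscle_z_fraction[2] * nz)
  expect_equal(which(lab == 1), z_lo:z_hi)
  expect_gt(sum(a$mask$voxels), 0)
})

test_that("mask voxels carry the muscle HU before noise (CLT bound)", {
  spec <- phantom_spec(shape = c(32, 64, 64), muscle_z_fraction = c(0.2, 0.8),
                       noise_sd = 10, seed = 9)
  ph <- generate_phantom(spec)
  inside <- ph$ct$voxels[ph$mask$voxels > 0]
  n <- length(inside)
  expect_lt(abs(mean(inside) - 55), 3 * 10 / sqrt(n))
  # noise-free phantom: exactly the muscle HU under the mask
  ph0 <- generate_phantom(phantom_spec(shape = c(16, 48, 48), noise_sd = 0,
                                       seed = 2))
  expect_true(all(ph0$ct$voxels[ph0$mask$voxels > 0] == 55))
  # tissue classes present at their nominal values
  expect_true(any(ph0$ct$voxels == -1000))   # air
  expect_true(any(ph0$ct$voxels == -800))    # lung
  expect_true(any(ph0$ct$voxels == -100))    # fat
  expect_true(any(ph0$ct$voxels == 700))     # bone
})

test_that("phantom volume matches the super-sampled construction within 5%", {
  for (seed in 1:3) {
    spec <- phantom_spec(shape = c(32, 96, 96), seed = seed,
                         muscle_thickness_px = 6 + seed, noise_sd = 0)
    ph <- generate_phantom(spec)
    q <- quantify_muscle(ph$ct, ph$mask)
    expected <- phantom_expected_volume(spec)
    expect_lt(abs(q$volume_cc - expected) / expected, 0.05)
  }
})

test_that("bilateral crescents form exactly two 3D components; distractors are removable", {
  spec <- phantom_spec(seed = 3, distractor_components = 4, noise_sd = 0)
  ph <- generate_phantom(spec)
  lab <- pectovol:::cpp_label_components(as.integer(ph$mask$voxels),
                                         dim(ph$mask$voxels)[1],
                                         dim(ph$mask$voxels)[2],
                                         dim(ph$mask$voxels)[3], 26L)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2)
  # distractor blobs share muscle HU but are disjoint from the mask:
  # a threshold mask at the muscle HU has extra components, and keeping the
  # two largest recovers the true mask
  thr <- array(as.integer(abs(ph$ct$voxels - 55) < 1e-9), dim = spec$shape)
  expect_gt(sum(thr), sum(ph$mask$voxels))
  cleaned <- connectivity_filter_3d(thr, 26, 2)
  expect_identical(array(as.integer(cleaned), dim = spec$shape),
                   array(as.integer(ph$mask$voxels), dim = spec$shape))
})

test_that("follow-up pairs scale the true mask volume as requested", {
  spec <- phantom_spec(seed = 11, noise_sd = 0)
  idp <- generate_followup_pair(spec, followup_perturbation(1, c(0, 0), 0,
                                                            seed = 12))
  v1 <- sum(idp$pre$mask$voxels); v2 <- sum(idp$post$mask$voxels)
  expect_lt(abs(100 * v1 / v2 - 100), 0.5)
  sc <- generate_followup_pair(spec,
                               followup_perturbation(1.10, c(1, -2), 0,
                                                     seed = 12))
  ratio <- sum(sc$post$mask$voxels) / sum(sc$pre$mask$voxels)
  expect_lt(abs(ratio - 1.10), 0.05 * 1.10)
  # same seeds -> identical pair
  again <- generate_followup_pair(spec,
                                  followup_perturbation(1.10, c(1, -2), 0,
                                                        seed = 12))
  expect_identical(again$post$ct$voxels, sc$post$ct$voxels)
})

test_that("training sets are reproducible with the requested dose mix", {
  set1 <- generate_training_set(10, seed = 77, shape = c(12, 32, 32))
  set2 <- generate_training_set(10, seed = 77, shape = c(12, 32, 32))
  expect_identical(lapply(set1, function(p) p$ct$voxels),
                   lapply(set2, function(p) p$ct$voxels))
  doses <- vapply(set1, function(p) p$ct$dose_tag, character(1))
  expect_equal(sum(doses == "low"), 7)   # low_dose_prop 0.7 of n = 10
  expect_true(all(vapply(set1, function(p) sum(p$mask$voxels) > 0,
                         logical(1))))
  # distinct geometries across the set
  vols <- vapply(set1, function(p) sum(p$mask$voxels), numeric(1))
  expect_gt(length(unique(vols)), 1)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(muscle_z_fraction = c(0.8, 0.2)))
  expect_error(phantom_spec(noise_sd = -1))
  expect_error(phantom_spec(shape = c(0, 10, 10)))
})
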