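test_that("small 2D components are removed against a labeling oracle", {
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L              # 100 px
  m[25, 25] <- 1L; m[25, 26] <- 1L; m[26, 25] <- 1L   # 3 px
  out <- filter_components_2d(m, min_px = 10)
  expect_equal(sum(out), 100)
  expect_equal(out[5:14, 5:14], matrix(1L, 10, 10))
  expect_equal(out[25, 25], 0L)
  # empty in, empty out; all-large is identity
  expect_equal(sum(filter_components_2d(matrix(0L, 5, 5), 10)), 0)
  expect_identical(filter_components_2d(m, 2), m)
  # 8-connectivity: a diagonal chain is one component
  diag_m <- matrix(0L, 6, 6); diag_m[cbind(1:5, 1:5)] <- 1L
  expect_equal(sum(filter_components_2d(diag_m, 5)), 5)
  expect_equal(sum(filter_components_2d(diag_m, 6)), 0)
})

test_that("2D filtering and 3D filtering are anti-extensive and idempotent", {
  set.seed(40)
  for (i in 1:10) {
    m <- matrix(as.integer(runif(400) > 0.7), 20, 20)
    f1 <- filter_components_2d(m, 5)
    expect_true(all(f1 <= m))
    expect_identical(filter_components_2d(f1, 5), f1)
  }
  v <- array(as.integer(runif(8 * 10 * 10) > 0.8), dim = c(8, 10, 10))
  c1 <- connectivity_filter_3d(v, 26, 2)
  expect_true(all(c1 <= v))
  expect_identical(connectivity_filter_3d(c1, 26, 2), c1)
})

test_that("morphological refinement fills holes and keeps convex solids", {
  solid <- matrix(0L, 30, 30); solid[6:25, 6:25] <- 1L
  expect_identical(morphological_refine(solid, radius = 2), solid)
  holed <- solid; holed[15, 15] <- 0L
  fixed <- morphological_refine(holed, radius = 2, fill_holes = TRUE)
  expect_equal(fixed[15, 15], 1L)
  expect_identical(fixed, solid)
  expect_equal(sum(morphological_refine(matrix(0L, 8, 8))), 0)
  # idempotence of closing + fill
  set.seed(41)
  m <- matrix(as.integer(runif(900) > 0.6), 30, 30)
  once <- morphological_refine(m, 2)
  expect_identical(morphological_refine(once, 2), once)
  # extensive only (never removes foreground)
  expect_true(all(once >= m))
})

test_that("3D connectivity filter keeps the largest components", {
  v <- array(0L, dim = c(10, 40, 40))
  v[2:9, 5:15, 5:20] <- 1L         # large no. 1
  v[2:9, 25:35, 5:20] <- 1L        # large no. 2
  v[3, 20, 30:33] <- 1L            # small blobs
  v[7, 2, 2] <- 1L
  v[9, 38, 38:39] <- 1L
  out <- connectivity_filter_3d(v, 26, 2)
  lab <- pectovol:::cpp_label_components(as.integer(out), 10L, 40L, 40L, 26L)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2)
  expect_equal(sum(out), sum(v[, 5:15, ] ) + sum(v[, 25:35, ]))
  # single component unchanged; empty unchanged
  single <- array(0L, dim = c(4, 6, 6)); single[2:3, 2:4, 2:4] <- 1L
  expect_identical(connectivity_filter_3d(single, 26, 2), single)
  expect_equal(sum(connectivity_filter_3d(array(0L, c(3, 4, 4)), 26, 2)), 0)
  # 6- vs 26-connectivity: diagonal touch splits under 6
  touch <- array(0L, dim = c(1, 4, 4))
  touch[1, 1:2, 1:2] <- 1L
  touch[1, 3:4, 3:4] <- 1L
  expect_equal(sum(connectivity_filter_3d(touch, 26, 1)), 8)  # one component
  expect_equal(sum(connectivity_filter_3d(touch, 6, 1)), 4)   # split
})

test_that("inter-slice interpolation bridges short gaps only", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  v <- array(0L, dim = c(7, 20, 20))
  v[3, , ] <- sq; v[5, , ] <- sq       # gap of one empty slice at z = 4
  out <- interpolate_between_slices(v, max_gap = 1)
  expect_equal(out[4, , ], sq)          # identical flanks reproduce the shape
  expect_equal(out[3, , ], sq)          # originals untouched
  expect_equal(out[5, , ], sq)
  expect_equal(sum(out[c(1, 2, 6, 7), , ]), 0)  # edge runs not bridged
  # gap of 3 with max_gap 1 stays untouched
  v2 <- array(0L, dim = c(7, 20, 20))
  v2[2, , ] <- sq; v2[6, , ] <- sq
  expect_identical(interpolate_between_slices(v2, max_gap = 1), v2)
  # no gaps -> identity
  v3 <- array(1L, dim = c(4, 6, 6))
  expect_identical(interpolate_between_slices(v3, 1), v3)
  # differing flanks give an intermediate contour within their union
  big <- matrix(0L, 20, 20); big[4:17, 4:17] <- 1L
  v4 <- array(0L, dim = c(3, 20, 20))
  v4[1, , ] <- sq; v4[3, , ] <- big
  out4 <- interpolate_between_slices(v4, 1)
  mid <- out4[2, , ]
  expect_true(all(mid[sq == 1 & big == 1] == 1) || sum(mid) > 0)
  expect_true(all(mid <= (sq | big)))
  expect_gte(sum(mid), sum(sq))
  expect_lte(sum(mid), sum(big))
})

test_that("full postprocess chain cleans a noisy bilateral mask", {
  sqL <- matrix(0L, 40, 40); sqL[8:20, 5:15] <- 1L
  sqR <- matrix(0L, 40, 40); sqR[8:20, 25:35] <- 1L
  v <- array(0L, dim = c(8, 40, 40))
  for (z in 2:7) v[z, , ] <- sqL + sqR
  v[4, , ] <- 0L                                   # dropped slice
  v[3, 30, 39] <- 1L                               # speckle
  v[5, 12, 10] <- 0L                               # hole
  mk <- mask_volume(v, spacing = c(1, 1, 3))
  # keep_components = 4: the dropped slice bisects each bilateral slab, so
  # the 3D filter (which runs before gap interpolation) sees four pieces
  out <- postprocess_mask(mk, postprocess_config(min_component_px = 10,
                                                 closing_radius = 1,
                                                 keep_components = 4))
  expect_equal(out$voxels[3, 30, 39], 0L)          # speckle removed
  expect_equal(out$voxels[5, 12, 10], 1L)          # hole filled
  expect_gt(sum(out$voxels[4, , ]), 0)             # gap bridged
})
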