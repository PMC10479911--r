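test_that("overlap metrics match direct voxel counting", {
  r <- array(0L, dim = c(3, 3, 3)); r[1, 1:3, 1] <- 1L; r[2, 1:3, 1] <- 1L
  t <- array(0L, dim = c(3, 3, 3)); t[1, 1:3, 1] <- 1L; t[1, 1, 2] <- 1L
  # |R| = 6, |T| = 4, |∩| = 3
  m <- segmentation_metrics(r, t)
  expect_equal(m$dsc, 0.6)
  expect_equal(m$iou, 3 / 7)
  expect_equal(m$precision, 0.5)
  expect_equal(m$pixel_accuracy, (27 - 4) / 27)
  # perfect and disjoint cases
  expect_equal(segmentation_metrics(r, r)$dsc, 1)
  disj <- array(0L, dim = c(3, 3, 3)); disj[3, 3, 3] <- 1L
  expect_equal(segmentation_metrics(r, disj)$dsc, 0)
  expect_equal(segmentation_metrics(r, disj)$iou, 0)
  # empty vs empty is perfect agreement
  e <- array(0L, dim = c(2, 2, 2))
  me <- segmentation_metrics(e, e)
  expect_equal(me$dsc, 1); expect_equal(me$iou, 1)
  expect_equal(me$precision, 1); expect_equal(me$pixel_accuracy, 1)
  expect_error(segmentation_metrics(r, array(0L, c(2, 2, 2))), "differ")
})

test_that("dsc = 2*iou/(1+iou) identically on random masks", {
  set.seed(50)
  for (i in 1:50) {
    r <- array(as.integer(runif(64) > runif(1)), dim = c(4, 4, 4))
    t <- array(as.integer(runif(64) > runif(1)), dim = c(4, 4, 4))
    m <- segmentation_metrics(r, t)
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-14)
    expect_gte(m$dsc, m$iou)
  }
})

test_that("volumetry: unit conversion, per-voxel conservation, mean HU", {
  v <- array(0L, dim = c(10, 10, 10)); v[1:10, 1:10, 1] <- 1L  # 100 voxels
  v[1:10, 1:10, 2] <- 1L; v[1:10, 1:10, 3] <- 1L; v[1:10, 1:10, 4] <- 1L
  v[1:10, 1:10, 5] <- 1L; v[1:10, 1:10, 6] <- 1L; v[1:10, 1:10, 7] <- 1L
  v[1:10, 1:10, 8] <- 1L; v[1:10, 1:10, 9] <- 1L; v[1:10, 1:10, 10] <- 1L
  stopifnot(sum(v) == 1000)
  ct <- ct_volume(array(50, dim = c(10, 10, 10)), spacing = c(1, 1, 1))
  mk <- mask_volume(v, spacing = c(1, 1, 1))
  q <- quantify_muscle(ct, mk)
  expect_equal(q$volume_cc, 1.000)
  expect_equal(q$mean_hu, 50)
  expect_equal(q$voxel_count, 1000)
  # conservation: volume == voxel_count * sx*sy*sz / 1000 at any spacing
  set.seed(51)
  for (i in 1:10) {
    sp <- runif(3, 0.5, 3)
    m2 <- array(as.integer(runif(4 * 5 * 6) > 0.5), dim = c(4, 5, 6))
    q2 <- quantify_muscle(ct_volume(array(0, c(4, 5, 6)), sp),
                          mask_volume(m2, sp))
    expect_equal(q2$volume_cc, sum(m2) * prod(sp) / 1000, tolerance = 1e-12)
    expect_equal(sum(q2$slice_areas_mm2) * sp[3] / 1000, q2$volume_cc,
                 tolerance = 1e-12)
  }
  empty <- mask_volume(array(0L, c(4, 5, 6)), c(1, 1, 1))
  qe <- quantify_muscle(ct_volume(array(0, c(4, 5, 6)), c(1, 1, 1)), empty)
  expect_equal(qe$volume_cc, 0)
  expect_true(is.na(qe$mean_hu))
})

test_that("rasterized ellipsoid volume matches the analytic value within 3%", {
  dims <- c(70, 50, 50)
  z <- (seq_len(dims[1]) - 0.5) - dims[1] / 2
  y <- (seq_len(dims[2]) - 0.5) - dims[2] / 2
  x <- (seq_len(dims[3]) - 0.5) - dims[3] / 2
  # semi-axes 30 (z), 20 (y), 15 (x) mm on a 1 mm grid
  ell <- outer(outer((z / 30)^2, (y / 20)^2, `+`), (x / 15)^2, `+`) <= 1
  mk <- mask_volume(array(as.integer(ell), dim = dims), spacing = c(1, 1, 1))
  ct <- ct_volume(array(55, dim = dims), spacing = c(1, 1, 1))
  q <- quantify_muscle(ct, mk)
  analytic <- 4 / 3 * pi * 30 * 20 * 15 / 1000
  expect_lt(abs(q$volume_cc - analytic) / analytic, 0.03)
})

test_that("follow-up comparison reports pre/post ratios and differences", {
  mkq <- function(vol_cc, hu) {
    ct <- ct_volume(array(hu, dim = c(10, 20, 20)), spacing = c(1, 1, 1))
    n_slice <- vol_cc * 1000 / 10 / 100   # rows of 100 voxels per slice
    v <- array(0L, dim = c(10, 20, 20))
    for (z in 1:10) v[z, 1:5, 1:20] <- 1L   # 100 voxels per slice
    stopifnot(sum(v) == 1000)
    quantify_muscle(ct, mask_volume(v, spacing = c(1, 1, 1)))
  }
  a <- mkq(1, 40); b <- mkq(1, 50)
  same <- compare_followup(a, a)
  expect_equal(same$ratio_volume_pct, 100)
  expect_equal(same$absdiff_volume_cc, 0)
  cmp <- compare_followup(a, b)
  expect_equal(cmp$absdiff_density_hu, 10)
  # pre 300 cc vs post 320 cc -> 93.75 %
  q300 <- structure(list(volume_cc = 300, mean_hu = 40, voxel_count = 1,
                         slice_areas_mm2 = 1), class = "muscle_quant")
  q320 <- structure(list(volume_cc = 320, mean_hu = 40, voxel_count = 1,
                         slice_areas_mm2 = 1), class = "muscle_quant")
  cmp2 <- compare_followup(q300, q320)
  expect_equal(cmp2$ratio_volume_pct, 93.75)
  expect_equal(cmp2$absdiff_volume_cc, 20)
  q0 <- structure(list(volume_cc = 0, mean_hu = NA_real_, voxel_count = 0,
                       slice_areas_mm2 = 0), class = "muscle_quant")
  expect_error(compare_followup(q300, q0), "zero")
})

test_that("the 2-SD rule flags a gross ratio outlier and only it", {
  mkq <- function(nvox) {
    v <- array(0L, dim = c(2, 20, 20)); v[1, seq_len(nvox %/% 20), ] <- 1L
    v[2, 1, seq_len(nvox %% 20)] <- 1L
    quantify_muscle(ct_volume(array(40, c(2, 20, 20)), c(1, 1, 1)),
                    mask_volume(v, c(1, 1, 1)))
  }
  post <- mkq(100)
  pres <- lapply(c(100, 98, 102, 100, 300), mkq)
  pairs <- lapply(pres, compare_followup, post = post)
  expect_equal(vapply(pairs, `[[`, numeric(1), "ratio_volume_pct"),
               c(100, 98, 102, 100, 300))
  flagged <- flag_outliers(pairs, k = 2)
  expect_equal(vapply(flagged, `[[`, logical(1), "outlier"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # equal ratios: nothing flagged
  eq <- lapply(rep(100, 4), function(n) compare_followup(mkq(n), post))
  expect_false(any(vapply(flag_outliers(eq), `[[`, logical(1), "outlier")))
  expect_error(flag_outliers(pairs[1:2]), "at least 3")
})

test_that("excluding flagged outliers never increases the retained SD", {
  set.seed(52)
  for (i in 1:20) {
    ratios <- c(rnorm(8, 100, 3), sample(c(150, 300, 40), 1))
    pairs <- lapply(ratios, function(r) {
      structure(list(ratio_volume_pct = r, ratio_density_pct = 100,
                     absdiff_volume_cc = 0, absdiff_density_hu = 0,
                     outlier = FALSE), class = "followup_comparison")
    })
    flagged <- flag_outliers(pairs, k = 2)
    keep <- !vapply(flagged, `[[`, logical(1), "outlier")
    if (sum(keep) >= 2 && sum(!keep) > 0) {
      expect_lte(sd(ratios[keep]), sd(ratios))
    }
  }
})
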