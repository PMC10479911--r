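test_that("range model maps any input size to out_bins logits, seeded", {
  pv <- asNamespace("pectovol")
  cfg <- range_model_config(encoder_width = 0.15, encoder_depth = 2,
                            out_bins = 32, seed = 9)
  m1 <- build_range_model(cfg)
  m2 <- build_range_model(cfg)
  expect_identical(m1$params, m2$params)   # seeded init
  for (hw in list(c(40, 30), c(64, 48), c(37, 29))) {
    x <- array(runif(prod(hw) * 3), dim = c(hw, 3, 1))
    fw <- pv$range_forward(m1, x, train = FALSE)
    expect_equal(dim(fw$logits), c(32L, 1L))
  }
})

test_that("dropout is active in training mode and inactive in eval mode", {
  pv <- asNamespace("pectovol")
  set.seed(30)
  x <- matrix(runif(50), 50, 1)
  tr <- pv$nn_dropout_fwd(x, 0.3, train = TRUE)
  ev <- pv$nn_dropout_fwd(x, 0.3, train = FALSE)
  expect_identical(ev$y, x)
  expect_gt(sum(tr$y == 0), 0)
  # surviving units are rescaled by 1/(1-p)
  kept <- tr$y != 0
  expect_equal(tr$y[kept], x[kept] / 0.7, tolerance = 1e-12)
})

test_that("seg config reproduces the 16-512 channel ladder and caps", {
  cfg <- seg_model_config(levels = 6, base_channels = 16, max_channels = 512)
  expect_equal(cfg$channels, c(16L, 32L, 64L, 128L, 256L, 512L))
  capped <- seg_model_config(levels = 6, base_channels = 16,
                             max_channels = 128)
  expect_equal(max(capped$channels), 128L)
  expect_error(seg_model_config(levels = 1), "levels")
})

test_that("seg model output matches input shape; attention adds parameters", {
  pv <- asNamespace("pectovol")
  cfg_on <- seg_model_config(levels = 3, base_channels = 4, max_channels = 16,
                             seed = 5)
  cfg_off <- seg_model_config(levels = 3, base_channels = 4,
                              max_channels = 16, attention_gates = FALSE,
                              final_attention = FALSE, seed = 5)
  m_on <- build_seg_model(cfg_on)
  m_off <- build_seg_model(cfg_off)
  expect_gt(pv$nn_count_params(m_on$params), pv$nn_count_params(m_off$params))
  x <- array(runif(16 * 24), dim = c(16, 24, 1, 2))
  for (m in list(m_on, m_off)) {
    fw <- pv$seg_forward(m, x, train = FALSE)
    expect_equal(dim(fw$prob), dim(x))
    expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  }
  expect_error(pv$seg_forward(m_on, array(0, c(18, 24, 1, 1)), FALSE),
               "divisible")
})

test_that("analytic gradients agree with numerical ones on a tiny U-Net", {
  pv <- asNamespace("pectovol")
  set.seed(31)
  cfg <- seg_model_config(levels = 2, base_channels = 2, max_channels = 4,
                          seed = 11)
  m <- build_seg_model(cfg)
  x <- array(runif(8 * 8), dim = c(8, 8, 1, 1))
  tgt <- matrix(as.integer(runif(64) > 0.6), 8, 8)
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    fw <- pv$seg_forward(mm, x, train = TRUE)
    dice_loss(fw$prob[, , 1, 1], tgt)
  }
  fw <- pv$seg_forward(m, x, train = TRUE)
  dprob <- array(pv$dice_loss_grad(fw$prob[, , 1, 1], tgt),
                 dim = dim(fw$prob))
  gr <- pv$seg_backward(fw$model, fw$cache, dprob)
  eps <- 1e-5
  for (nm in c("enc1_c1_W", "enc2_c2_W", "dec1_c1_W", "att1_Wg", "fatt_W",
               "head_W", "enc1_bn1_g", "up1_W")) {
    idx <- 1L
    p1 <- m$params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- m$params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
    expect_equal(gr[[nm]][idx], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("median vote aggregation reproduces the worked example", {
  votes <- rbind(c(1, 1, 1, 0, 0),
                 c(0, 1, 1, 1, 0),
                 c(0, 1, 1, 0, 0),
                 c(1, 1, 1, 1, 0),
                 c(0, 0, 1, 1, 0))
  agg <- aggregate_range_votes(votes)
  expect_equal(agg$binary, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(agg$interval, c(2L, 5L))   # 0-based [1, 4)
  # all views identical -> median equals any view
  same <- matrix(rep(c(0, 1, 1, 0, 0), each = 3), nrow = 3)
  expect_equal(aggregate_range_votes(same)$binary, c(0L, 1L, 1L, 0L, 0L))
  # all-zero aggregation -> empty interval
  expect_equal(aggregate_range_votes(matrix(0, 3, 6))$interval, c(1L, 1L))
  # even-count tie at 0.5 rounds up to 1
  expect_equal(aggregate_range_votes(rbind(c(1, 0), c(0, 0)))$binary,
               c(1L, 0L))
})

test_that("median aggregation equals the brute-force oracle up to 7 views", {
  set.seed(33)
  for (nv in c(3, 5, 7)) {
    for (rep in 1:20) {
      votes <- matrix(as.integer(runif(nv * 20) > 0.5), nv, 20)
      got <- aggregate_range_votes(votes)
      want <- oracle_median_interval(votes)
      expect_identical(got$binary, want$binary)
      expect_identical(got$interval, as.integer(want$interval))
    }
  }
})

test_that("range training is reproducible, learns, and transfers", {
  set.seed(34)
  # small synthetic task: bright band rows indicate presence
  make_case <- function(seed) {
    set.seed(seed)
    lo <- sample(4:10, 1); hi <- lo + sample(6:10, 1)
    img <- array(runif(24 * 16 * 3, 0, 0.2), dim = c(24, 16, 3))
    img[lo:hi, , ] <- img[lo:hi, , ] + 0.6
    lab <- integer(24); lab[lo:hi] <- 1L
    list(img = img, lab = lab)
  }
  cases <- lapply(1:30, make_case)
  imgs <- lapply(cases, `[[`, "img")
  labs <- lapply(cases, `[[`, "lab")
  cfg <- range_model_config(encoder_width = 0.15, encoder_depth = 2,
                            out_bins = 24, seed = 3)
  m1 <- train_range_model(build_range_model(cfg), imgs, labs, epochs = 4,
                          seed = 11)
  m2 <- train_range_model(build_range_model(cfg), imgs, labs, epochs = 4,
                          seed = 11)
  expect_identical(m1$report$loss_history, m2$report$loss_history)
  expect_lt(m1$report$loss_history[4], m1$report$loss_history[1])
  # warm start from trained weights beats a cold start in epoch 1
  warm <- train_range_model(build_range_model(cfg), imgs, labs, epochs = 1,
                            seed = 12,
                            init_weights = list(params = m1$params,
                                                state = m1$state))
  cold <- train_range_model(build_range_model(cfg), imgs, labs, epochs = 1,
                            seed = 12)
  expect_lt(warm$report$loss_history[1], cold$report$loss_history[1])
  expect_error(train_range_model(build_range_model(cfg), list(), list()),
               "empty")
})

test_that("seg training splits 8:2, is deterministic and reduces the loss", {
  set.seed(35)
  sp <- split_dataset(1:100, ratio = 0.8, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$validation, 20)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:100)

  mk_slice <- function(seed) {
    set.seed(seed)
    m <- matrix(0L, 16, 16)
    r <- sample(3:10, 1)
    m[r:(r + 4), 4:12] <- 1L
    img <- matrix(runif(256, 0, 0.3), 16, 16) + 0.5 * m
    list(img = img, m = m)
  }
  cases <- lapply(1:20, mk_slice)
  slices <- lapply(cases, `[[`, "img")
  masks <- lapply(cases, `[[`, "m")
  cfg <- seg_model_config(levels = 2, base_channels = 4, max_channels = 8,
                          seed = 2)
  t1 <- train_seg_model(build_seg_model(cfg), slices, masks, epochs = 5,
                        lr = 3e-3, seed = 8)
  t2 <- train_seg_model(build_seg_model(cfg), slices, masks, epochs = 5,
                        lr = 3e-3, seed = 8)
  expect_identical(t1$report$loss_history, t2$report$loss_history)
  expect_lt(t1$report$loss_history[5], t1$report$loss_history[1])
  expect_equal(t1$report$n_train, 16)
  expect_equal(t1$report$n_val, 4)
  expect_error(train_seg_model(build_seg_model(cfg), list(), list()), "empty")
})

test_that("predict_slice_masks honours the interval contract", {
  models <- tiny_trained_models()
  ph <- models$train[[1]]
  d <- dim(ph$ct$voxels)
  expect_warning(
    empty <- predict_slice_masks(models$seg, ph$ct, c(1L, 1L)),
    "empty")
  expect_equal(sum(empty$voxels), 0)
  expect_equal(dim(empty$voxels), d)
  nz <- d[1]
  tz <- which(rowSums(matrix(ph$mask$voxels, nrow = nz)) > 0)
  pred <- predict_slice_masks(models$seg, ph$ct,
                              c(min(tz), max(tz) + 1L))
  expect_equal(dim(pred$voxels), d)
  outside <- setdiff(seq_len(nz), min(tz):max(tz))
  expect_equal(sum(pred$voxels[outside, , ]), 0)
  expect_gt(sum(pred$voxels), 0)   # a trained model finds muscle in range
})

test_that("predict_range recovers the phantom interval approximately", {
  models <- tiny_trained_models()
  ph <- models$train[[2]]
  iso <- resample_isotropic(ph$ct, 2)
  pr <- predict_range(models$range, iso, n_views = 5, seed = 21)
  expect_false(pr$empty)
  nz <- dim(ph$mask$voxels)[1]
  tz <- which(rowSums(matrix(ph$mask$voxels, nrow = nz)) > 0)
  # overlap between predicted and true slice ranges
  pred_z <- pr$slice_interval[1]:(pr$slice_interval[2] - 1)
  expect_gt(length(intersect(pred_z, tz)), 0)
  expect_error(predict_range(build_range_model(range_model_config()), iso),
               "trained")
})
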