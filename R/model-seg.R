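#' Configuration for the slice-segmentation model
#'
#' An attention-gated U-Net operating on single axial CT slices. Encoder and
#' decoder each have `levels` resolution levels; level k carries
#' `min(base_channels * 2^(k-1), max_channels)` channels (the default
#' 6-level, 16-channel base yields the 16-512 ladder). Every level applies
#' two 3x3 convolutions, each followed by batch normalization and ReLU;
#' downsampling is 2x2 max pooling, upsampling nearest-neighbour x2 followed
#' by a 3x3 convolution. When `attention_gates` is on, each skip connection
#' is weighted by an additive attention gate driven by the coarser decoder
#' feature; `final_attention` adds one more spatial attention block on the
#' last feature map before the output head.
#'
#' @param levels encoder/decoder depth (>= 2, default 6).
#' @param base_channels channels at the finest level (default 16).
#' @param max_channels channel cap (default 512).
#' @param attention_gates,final_attention architecture switches (default on).
#' @param seed integer seed for weight initialization.
#' @return A `seg_model_config` list; `$channels` holds the per-level ladder.
#' @export
seg_model_config <- function(levels = 6, base_channels = 16,
                             max_channels = 512, attention_gates = TRUE,
                             final_attention = TRUE, seed = 1) {
  stopifnot(levels >= 2, base_channels >= 1, max_channels >= base_channels)
  channels <- pmin(base_channels * 2^(seq_len(levels) - 1), max_channels)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 channels = as.integer(channels),
                 attention_gates = isTRUE(attention_gates),
                 final_attention = isTRUE(final_attention),
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

#' Build a slice-segmentation model
#'
#' Allocates seeded initial weights for the attention U-Net described in
#' [seg_model_config()]. Spatial input sizes must be divisible by
#' `2^(levels - 1)`; [predict_slice_masks()] pads and crops automatically.
#'
#' @param cfg a [seg_model_config()].
#' @return A `seg_model` object.
#' @export
build_seg_model <- function(cfg) {
  stopifnot(inherits(cfg, "seg_model_config"))
  L <- cfg$levels
  ch <- cfg$channels
  params <- list()
  state <- list()
  add_bn <- function(nm, c) {
    params[[paste0(nm, "_g")]] <<- rep(1, c)
    params[[paste0(nm, "_be")]] <<- numeric(c)
    state[[nm]] <<- list(rmean = numeric(c), rvar = rep(1, c))
  }
  with_seed(cfg$seed, {
    cin <- 1L
    for (k in seq_len(L)) {
      params[[paste0("enc", k, "_c1_W")]] <- nn_he_init(3, cin, ch[k])
      params[[paste0("enc", k, "_c1_b")]] <- numeric(ch[k])
      add_bn(paste0("enc", k, "_bn1"), ch[k])
      params[[paste0("enc", k, "_c2_W")]] <- nn_he_init(3, ch[k], ch[k])
      params[[paste0("enc", k, "_c2_b")]] <- numeric(ch[k])
      add_bn(paste0("enc", k, "_bn2"), ch[k])
      cin <- ch[k]
    }
    for (k in rev(seq_len(L - 1))) {
      params[[paste0("up", k, "_W")]] <- nn_he_init(3, ch[k + 1], ch[k])
      params[[paste0("up", k, "_b")]] <- numeric(ch[k])
      if (cfg$attention_gates) {
        ci <- max(ch[k] %/% 2L, 1L)
        params[[paste0("att", k, "_Wg")]] <- nn_he_init(1, ch[k], ci)
        params[[paste0("att", k, "_bg")]] <- numeric(ci)
        params[[paste0("att", k, "_Wx")]] <- nn_he_init(1, ch[k], ci)
        params[[paste0("att", k, "_bx")]] <- numeric(ci)
        params[[paste0("att", k, "_Wp")]] <- nn_he_init(1, ci, 1)
        params[[paste0("att", k, "_bp")]] <- numeric(1)
      }
      params[[paste0("dec", k, "_c1_W")]] <- nn_he_init(3, 2L * ch[k], ch[k])
      params[[paste0("dec", k, "_c1_b")]] <- numeric(ch[k])
      add_bn(paste0("dec", k, "_bn1"), ch[k])
      params[[paste0("dec", k, "_c2_W")]] <- nn_he_init(3, ch[k], ch[k])
      params[[paste0("dec", k, "_c2_b")]] <- numeric(ch[k])
      add_bn(paste0("dec", k, "_bn2"), ch[k])
    }
    if (cfg$final_attention) {
      params$fatt_W <- nn_he_init(1, ch[1], 1)
      params$fatt_b <- numeric(1)
    }
    params$head_W <- nn_he_init(1, ch[1], 1)
    params$head_b <- numeric(1)
  })
  structure(list(params = params, state = state, cfg = cfg,
                 trained = FALSE, epochs_trained = 0L),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %d levels, channels %s, attention %s/%s, %s (%d params)\n",
              x$cfg$levels, paste(x$cfg$channels, collapse = "/"),
              ifelse(x$cfg$attention_gates, "gates", "no-gates"),
              ifelse(x$cfg$final_attention, "final", "no-final"),
              if (x$trained) sprintf("trained %d epochs", x$epochs_trained)
              else "untrained",
              nn_count_params(x$params)))
  invisible(x)
}

# One conv/bn/relu/conv/bn/relu block; returns y, updated state, cache.
seg_block_fwd <- function(model, nm, x, train) {
  p <- model$params
  c1 <- nn_conv_fwd(x, p[[paste0(nm, "_c1_W")]], p[[paste0(nm, "_c1_b")]])
  b1 <- nn_bn_fwd(c1$y, p[[paste0(nm, "_bn1_g")]], p[[paste0(nm, "_bn1_be")]],
                  model$state[[paste0(nm, "_bn1")]], train)
  model$state[[paste0(nm, "_bn1")]] <- b1$state
  r1 <- nn_relu_fwd(b1$y)
  c2 <- nn_conv_fwd(r1$y, p[[paste0(nm, "_c2_W")]], p[[paste0(nm, "_c2_b")]])
  b2 <- nn_bn_fwd(c2$y, p[[paste0(nm, "_bn2_g")]], p[[paste0(nm, "_bn2_be")]],
                  model$state[[paste0(nm, "_bn2")]], train)
  model$state[[paste0(nm, "_bn2")]] <- b2$state
  r2 <- nn_relu_fwd(b2$y)
  list(y = r2$y, model = model,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

seg_block_bwd <- function(nm, cache, dy, grads) {
  dy <- nn_relu_bwd(cache$r2, dy)
  bb <- nn_bn_bwd(cache$b2, dy)
  grads[[paste0(nm, "_bn2_g")]] <- bb$dgamma
  grads[[paste0(nm, "_bn2_be")]] <- bb$dbeta
  cb <- nn_conv_bwd(cache$c2, bb$dx)
  grads[[paste0(nm, "_c2_W")]] <- cb$dw
  grads[[paste0(nm, "_c2_b")]] <- cb$db
  dy <- nn_relu_bwd(cache$r1, cb$dx)
  bb <- nn_bn_bwd(cache$b1, dy)
  grads[[paste0(nm, "_bn1_g")]] <- bb$dgamma
  grads[[paste0(nm, "_bn1_be")]] <- bb$dbeta
  cb <- nn_conv_bwd(cache$c1, bb$dx)
  grads[[paste0(nm, "_c1_W")]] <- cb$dw
  grads[[paste0(nm, "_c1_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

# Sum an (H, W, C, N) tensor over its channel axis -> (H, W, 1, N).
sum_channels <- function(x) {
  d <- dim(x)
  s <- rowSums(matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]))
  array(s, dim = c(d[1], d[2], 1L, d[4]))
}

# Additive attention gate: alpha = sigmoid(psi(relu(Wg g + Wx x))), y = x alpha.
att_gate_fwd <- function(p, k, g, x) {
  nm <- paste0("att", k)
  ag <- nn_conv_fwd(g, p[[paste0(nm, "_Wg")]], p[[paste0(nm, "_bg")]],
                    stride = 1L, pad = 0L)
  ax <- nn_conv_fwd(x, p[[paste0(nm, "_Wx")]], p[[paste0(nm, "_bx")]],
                    stride = 1L, pad = 0L)
  a <- ag$y + ax$y
  r <- nn_relu_fwd(a)
  s <- nn_conv_fwd(r$y, p[[paste0(nm, "_Wp")]], p[[paste0(nm, "_bp")]],
                   stride = 1L, pad = 0L)
  alpha <- nn_sigmoid(s$y)
  list(y = nn_gate_mul(x, alpha),
       cache = list(ag = ag$cache, ax = ax$cache, r = r$cache, s = s$cache,
                    alpha = alpha, x = x))
}

att_gate_bwd <- function(k, cache, dy, grads) {
  nm <- paste0("att", k)
  alpha <- cache$alpha
  x <- cache$x
  dx1 <- nn_gate_mul(dy, alpha)
  dalpha <- sum_channels(dy * x)
  ds <- dalpha * alpha * (1 - alpha)
  cb <- nn_conv_bwd(cache$s, ds)
  grads[[paste0(nm, "_Wp")]] <- cb$dw
  grads[[paste0(nm, "_bp")]] <- cb$db
  da <- nn_relu_bwd(cache$r, cb$dx)
  cg <- nn_conv_bwd(cache$ag, da)
  grads[[paste0(nm, "_Wg")]] <- cg$dw
  grads[[paste0(nm, "_bg")]] <- cg$db
  cx <- nn_conv_bwd(cache$ax, da)
  grads[[paste0(nm, "_Wx")]] <- cx$dw
  grads[[paste0(nm, "_bx")]] <- cx$db
  list(dx = dx1 + cx$dx, dg = cg$dx, grads = grads)
}

# Full forward: x (H, W, 1, N) -> probability map of the same shape.
seg_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  L <- cfg$levels
  d <- dim(x)
  div <- 2^(L - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input size must be divisible by ", div,
         " (use predict_slice_masks for automatic padding)")
  }
  cache <- list(enc = vector("list", L), pool = vector("list", L - 1),
                dec = vector("list", L - 1))
  skips <- vector("list", L)
  h <- x
  for (k in seq_len(L)) {
    if (k > 1) {
      pl <- nn_maxpool_fwd(h)
      cache$pool[[k - 1]] <- pl$cache
      h <- pl$y
    }
    blk <- seg_block_fwd(model, paste0("enc", k), h, train)
    model <- blk$model
    cache$enc[[k]] <- blk$cache
    h <- blk$y
    skips[[k]] <- h
  }
  dcur <- h
  for (k in rev(seq_len(L - 1))) {
    e <- skips[[k]]
    up <- nn_up2_fwd(dcur, target_hw = dim(e)[1:2])
    uc <- nn_conv_fwd(up$y, model$params[[paste0("up", k, "_W")]],
                      model$params[[paste0("up", k, "_b")]])
    ur <- nn_relu_fwd(uc$y)
    g <- ur$y
    if (cfg$attention_gates) {
      at <- att_gate_fwd(model$params, k, g, e)
      s <- at$y
      at_cache <- at$cache
    } else {
      s <- e
      at_cache <- NULL
    }
    h2 <- nn_concat(s, g)
    blk <- seg_block_fwd(model, paste0("dec", k), h2, train)
    model <- blk$model
    cache$dec[[k]] <- list(up = up$cache, uc = uc$cache, ur = ur$cache,
                           at = at_cache, blk = blk$cache,
                           c_skip = dim(e)[3])
    dcur <- blk$y
  }
  if (cfg$final_attention) {
    fs <- nn_conv_fwd(dcur, model$params$fatt_W, model$params$fatt_b,
                      stride = 1L, pad = 0L)
    falpha <- nn_sigmoid(fs$y)
    gated <- nn_gate_mul(dcur, falpha)
    cache$fatt <- list(s = fs$cache, alpha = falpha, x = dcur)
    dcur <- gated
  }
  hd <- nn_conv_fwd(dcur, model$params$head_W, model$params$head_b,
                    stride = 1L, pad = 0L)
  prob <- nn_sigmoid(hd$y)
  cache$head <- hd$cache
  cache$prob <- prob
  list(prob = prob, model = model, cache = cache)
}

seg_backward <- function(model, cache, dprob) {
  cfg <- model$cfg
  L <- cfg$levels
  grads <- list()
  dlogit <- dprob * cache$prob * (1 - cache$prob)
  cb <- nn_conv_bwd(cache$head, dlogit)
  grads$head_W <- cb$dw
  grads$head_b <- cb$db
  dcur <- cb$dx
  if (cfg$final_attention) {
    fa <- cache$fatt
    dx1 <- nn_gate_mul(dcur, fa$alpha)
    dalpha <- sum_channels(dcur * fa$x)
    ds <- dalpha * fa$alpha * (1 - fa$alpha)
    cb <- nn_conv_bwd(fa$s, ds)
    grads$fatt_W <- cb$dw
    grads$fatt_b <- cb$db
    dcur <- dx1 + cb$dx
  }
  dskip <- vector("list", L)
  for (k in seq_len(L - 1)) {
    dc <- cache$dec[[k]]
    bb <- seg_block_bwd(paste0("dec", k), dc$blk, dcur, grads)
    grads <- bb$grads
    cs <- dc$c_skip
    d_all <- bb$dx
    d_s <- d_all[, , seq_len(cs), , drop = FALSE]
    d_g <- d_all[, , cs + seq_len(dim(d_all)[3] - cs), , drop = FALSE]
    if (cfg$attention_gates) {
      ab <- att_gate_bwd(k, dc$at, d_s, grads)
      grads <- ab$grads
      dskip[[k]] <- ab$dx
      d_g <- d_g + ab$dg
    } else {
      dskip[[k]] <- d_s
    }
    d_g <- nn_relu_bwd(dc$ur, d_g)
    cb <- nn_conv_bwd(dc$uc, d_g)
    grads[[paste0("up", k, "_W")]] <- cb$dw
    grads[[paste0("up", k, "_b")]] <- cb$db
    dcur <- nn_up2_bwd(dc$up, cb$dx)
  }
  for (k in rev(seq_len(L))) {
    dh <- if (k == L) dcur else dskip[[k]] + dnext
    bb <- seg_block_bwd(paste0("enc", k), cache$enc[[k]], dh, grads)
    grads <- bb$grads
    if (k > 1) {
      dnext <- nn_maxpool_bwd(cache$pool[[k - 1]], bb$dx)
    }
  }
  grads
}

#' Train the slice-segmentation model
#'
#' Mini-batch Adam on the soft Dice loss, computed per sample and averaged
#' over the batch. The dataset is split into training and validation parts
#' at `split_ratio` (default 8:2) with a seeded shuffle. Optional paired
#' augmentation ([augment_sample()]) can be applied on the fly.
#'
#' @param model a [build_seg_model()] handle.
#' @param slices list of 2D normalized-intensity matrices (all one size,
#'   divisible by `2^(levels-1)`).
#' @param masks list of matching binary matrices.
#' @param epochs,lr,batch optimizer settings.
#' @param seed seed for the split, shuffling and augmentation.
#' @param split_ratio training fraction (default 0.8).
#' @param augment_ops augmentation ops applied to training samples, or
#'   `NULL`/empty for none.
#' @param init_weights optional `list(params =, state =)` to start from
#'   (transfer learning between active-learning rounds).
#' @return The trained `seg_model` with a `report` field (`train_report`):
#'   per-epoch mean Dice loss and final validation Dice loss.
#' @export
train_seg_model <- function(model, slices, masks, epochs = 8, lr = 1e-3,
                            batch = 8, seed = 1, split_ratio = 0.8,
                            augment_ops = NULL, init_weights = NULL) {
  stopifnot(inherits(model, "seg_model"))
  if (length(slices) == 0) stop("empty dataset")
  if (length(slices) != length(masks)) stop("slices/masks length mismatch")
  if (!is.null(init_weights)) {
    model$params <- init_weights$params
    model$state <- init_weights$state
  }
  n <- length(slices)
  opt <- adam_init(model$params)
  loss_hist <- numeric(epochs)
  final_acc <- NA_real_
  with_seed(seed, {
    sp <- split_dataset(seq_len(n), ratio = split_ratio,
                        seed = stats::runif(1) * 1e6)
    tr_idx <- sp$train
    val_idx <- sp$validation
    for (ep in seq_len(epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      bl <- 0; acc <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch)) {
        ids <- ord[start:min(start + batch - 1, length(ord))]
        xs <- slices[ids]
        ys <- masks[ids]
        if (length(augment_ops)) {
          for (i in seq_along(ids)) {
            au <- augment_sample(xs[[i]], ys[[i]], ops = augment_ops,
                                 seed = floor(stats::runif(1) * 2^30))
            xs[[i]] <- au$image
            ys[[i]] <- au$mask
          }
        }
        x <- stack_images(lapply(xs, function(m) array(m, dim = c(dim(m), 1L))))
        fw <- seg_forward(model, x, train = TRUE)
        model <- fw$model
        nb1 <- length(ids)
        dprob <- array(0, dim = dim(fw$prob))
        loss <- 0
        for (i in seq_len(nb1)) {
          p_i <- fw$prob[, , 1, i]
          t_i <- ys[[i]]
          loss <- loss + dice_loss(p_i, t_i) / nb1
          dprob[, , 1, i] <- dice_loss_grad(p_i, t_i) / nb1
          acc_i <- mean((p_i >= 0.5) == (t_i > 0.5))
          acc <- acc + acc_i / nb1
        }
        grads <- seg_backward(model, fw$cache, dprob)
        st <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- st$params; opt <- st$opt
        bl <- bl + loss
        nb <- nb + 1
      }
      loss_hist[ep] <- bl / nb
      final_acc <- acc / nb
    }
    val_loss <- if (length(val_idx)) {
      vl <- 0
      for (i in val_idx) {
        x <- array(slices[[i]], dim = c(dim(slices[[i]]), 1L, 1L))
        fw <- seg_forward(model, x, train = FALSE)
        vl <- vl + dice_loss(fw$prob[, , 1, 1], masks[[i]]) / length(val_idx)
      }
      vl
    } else NA_real_
    model$report <- train_report(loss_hist, final_acc, val_loss, seed, epochs,
                                 n_train = length(tr_idx),
                                 n_val = length(val_idx))
  })
  model$trained <- TRUE
  model$epochs_trained <- model$epochs_trained + as.integer(epochs)
  model
}

#' Segment axial slices within a detected range
#'
#' Runs the trained U-Net on every original axial CT slice inside the
#' half-open `slice_interval`; slices outside the interval are left empty.
#' Each slice is window-normalized, zero-padded (bottom/right) up to the
#' nearest multiple of `2^(levels-1)`, segmented, thresholded, and cropped
#' back. An empty interval returns an all-zero mask with a warning.
#'
#' @param model trained `seg_model`.
#' @param ct a [ct_volume()].
#' @param slice_interval 1-based half-open `c(lo, hi)`.
#' @param window HU window for [normalize_intensity()].
#' @param threshold probability cutoff (default 0.5).
#' @param batch slices per forward pass.
#' @return A [mask_volume()] with the CT's shape and spacing.
#' @export
predict_slice_masks <- function(model, ct, slice_interval,
                                window = c(-200, 300), threshold = 0.5,
                                batch = 8) {
  stopifnot(inherits(model, "seg_model"), inherits(ct, "ct_volume"))
  if (!model$trained) stop("segmentation model has not been trained")
  d <- dim(ct$voxels)
  out <- array(0L, dim = d)
  lo <- slice_interval[1]; hi <- slice_interval[2]
  if (hi <= lo) {
    warning("empty slice interval; returning empty mask")
    return(mask_volume(out, ct$spacing, ct$origin, ct$source_id))
  }
  if (lo < 1 || hi > d[1] + 1) stop("slice interval outside volume")
  div <- 2^(model$cfg$levels - 1)
  Hp <- as.integer(ceiling(d[2] / div) * div)
  Wp <- as.integer(ceiling(d[3] / div) * div)
  zs <- lo:(hi - 1)
  for (start in seq(1, length(zs), by = batch)) {
    ids <- zs[start:min(start + batch - 1, length(zs))]
    x <- array(0, dim = c(Hp, Wp, 1L, length(ids)))
    for (i in seq_along(ids)) {
      x[seq_len(d[2]), seq_len(d[3]), 1, i] <-
        normalize_intensity(ct$voxels[ids[i], , ], window)
    }
    fw <- seg_forward(model, x, train = FALSE)
    for (i in seq_along(ids)) {
      out[ids[i], , ] <-
        (fw$prob[seq_len(d[2]), seq_len(d[3]), 1, i] >= threshold) + 0L
    }
  }
  mask_volume(out, ct$spacing, ct$origin, ct$source_id)
}
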