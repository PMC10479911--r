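#' Configuration for the range-detection model
#'
#' The detector is a compact convolutional encoder with compound
#' width/depth scaling in the spirit of the EfficientNet family: block k
#' carries `round(32 * encoder_width * 2^(k-1))` channels (minimum 4), each
#' block being conv 3x3 / batch norm / ReLU / 2x2 max pool. An adaptive
#' average pooling layer then linearizes the feature map to a fixed 8x4 grid
#' regardless of the input's spatial size — scan length varies between
#' acquisitions, so the head must be size-independent — followed by dropout
#' and a single linear layer producing `out_bins` logits, one per vertical
#' position bin.
#'
#' @param encoder_width channel multiplier (default 0.25, the desk-scale
#'   configuration).
#' @param encoder_depth number of conv blocks (default 3).
#' @param dropout dropout probability before the linear head (default 0.3).
#' @param out_bins fixed number of output bins (default 128, >= 8).
#' @param threshold probability cutoff for binarizing presence (default 0.5).
#' @param seed integer seed for weight initialization.
#' @return A `range_model_config` list.
#' @export
range_model_config <- function(encoder_width = 0.25, encoder_depth = 3,
                               dropout = 0.3, out_bins = 128,
                               threshold = 0.5, seed = 1) {
  stopifnot(encoder_width > 0, encoder_depth >= 1,
            dropout >= 0, dropout < 1, out_bins >= 8,
            threshold > 0, threshold < 1)
  widths <- pmax(4L, as.integer(round(32 * encoder_width *
                                        2^(seq_len(encoder_depth) - 1))))
  structure(list(encoder_width = encoder_width,
                 encoder_depth = as.integer(encoder_depth),
                 widths = widths, dropout = dropout,
                 out_bins = as.integer(out_bins), threshold = threshold,
                 pool_hw = c(8L, 4L), seed = as.integer(seed)),
            class = "range_model_config")
}

#' Build a range-detection model
#'
#' Allocates seeded initial weights for the architecture described in
#' [range_model_config()]. The handle is an S3 object holding the flat
#' parameter list, batch-norm running statistics, and the config; it is
#' trained with [train_range_model()] and applied with [predict_range()].
#'
#' @param cfg a [range_model_config()].
#' @return A `range_model` object.
#' @export
build_range_model <- function(cfg) {
  stopifnot(inherits(cfg, "range_model_config"))
  params <- list()
  state <- list()
  with_seed(cfg$seed, {
    cin <- 3L
    for (k in seq_len(cfg$encoder_depth)) {
      ck <- cfg$widths[k]
      params[[paste0("b", k, "_W")]] <- nn_he_init(3, cin, ck)
      params[[paste0("b", k, "_b")]] <- numeric(ck)
      params[[paste0("b", k, "_g")]] <- rep(1, ck)
      params[[paste0("b", k, "_be")]] <- numeric(ck)
      state[[paste0("b", k)]] <- list(rmean = numeric(ck), rvar = rep(1, ck))
      cin <- ck
    }
    feat <- cin * prod(cfg$pool_hw)
    params$fc_W <- matrix(stats::rnorm(cfg$out_bins * feat,
                                       sd = sqrt(1 / feat)),
                          cfg$out_bins, feat)
    params$fc_b <- numeric(cfg$out_bins)
  })
  structure(list(params = params, state = state, cfg = cfg,
                 trained = FALSE, epochs_trained = 0L),
            class = "range_model")
}

#' @export
print.range_model <- function(x, ...) {
  cat(sprintf("<range_model> depth %d, widths %s, out_bins %d, %s (%d params)\n",
              x$cfg$encoder_depth, paste(x$cfg$widths, collapse = "/"),
              x$cfg$out_bins,
              if (x$trained) sprintf("trained %d epochs", x$epochs_trained)
              else "untrained",
              nn_count_params(x$params)))
  invisible(x)
}

# Forward pass: x is (H, W, 3, N); returns (out_bins x N) logits + cache.
range_forward <- function(model, x, train = FALSE) {
  p <- model$params
  cfg <- model$cfg
  cache <- list()
  h <- x
  for (k in seq_len(cfg$encoder_depth)) {
    cv <- nn_conv_fwd(h, p[[paste0("b", k, "_W")]], p[[paste0("b", k, "_b")]])
    bn <- nn_bn_fwd(cv$y, p[[paste0("b", k, "_g")]], p[[paste0("b", k, "_be")]],
                    model$state[[paste0("b", k)]], train)
    model$state[[paste0("b", k)]] <- bn$state
    rl <- nn_relu_fwd(bn$y)
    pl <- nn_maxpool_fwd(rl$y)
    cache[[k]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                       pl = pl$cache)
    h <- pl$y
  }
  ap <- nn_adaptive_pool_fwd(h, cfg$pool_hw[1], cfg$pool_hw[2])
  N <- dim(h)[4]
  flat <- matrix(ap$y, ncol = N)
  dp <- nn_dropout_fwd(flat, cfg$dropout, train)
  fc <- nn_linear_fwd(dp$y, p$fc_W, p$fc_b)
  list(logits = fc$y, model = model,
       cache = list(blocks = cache, ap = ap$cache, dp = dp$cache,
                    fc = fc$cache, pooled_dim = dim(ap$y)))
}

range_backward <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list()
  fb <- nn_linear_bwd(cache$fc, dlogits)
  grads$fc_W <- fb$dw; grads$fc_b <- fb$db
  dflat <- nn_dropout_bwd(cache$dp, fb$dx)
  dh <- nn_adaptive_pool_bwd(cache$ap, array(dflat, dim = cache$pooled_dim))
  for (k in rev(seq_len(model$cfg$encoder_depth))) {
    ck <- cache$blocks[[k]]
    dh <- nn_maxpool_bwd(ck$pl, dh)
    dh <- nn_relu_bwd(ck$rl, dh)
    bb <- nn_bn_bwd(ck$bn, dh)
    grads[[paste0("b", k, "_g")]] <- bb$dgamma
    grads[[paste0("b", k, "_be")]] <- bb$dbeta
    cb <- nn_conv_bwd(ck$cv, bb$dx)
    grads[[paste0("b", k, "_W")]] <- cb$dw
    grads[[paste0("b", k, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

# Nearest-neighbour resampling of a label/probability vector to a new length.
resample_vector <- function(v, n_new, binary = FALSE) {
  n <- length(v)
  if (n == n_new) return(v)
  idx <- pmin(pmax(round((seq_len(n_new) - 0.5) * n / n_new + 0.5), 1), n)
  out <- v[idx]
  if (binary) out <- as.integer(out > 0.5)
  out
}

#' Train the range-detection model
#'
#' Mini-batch Adam on binary cross-entropy with logits. Per-sample labels
#' (one presence bit per isotropic z slice) are nearest-resampled to the
#' model's fixed `out_bins`. A seeded fraction of the samples is held out
#' for validation. Passing `init_weights` (the `params`/`state` of a
#' previously trained model) starts from those weights instead of the fresh
#' initialization — the transfer-learning path used between active-learning
#' rounds.
#'
#' @param model a [build_range_model()] handle.
#' @param images list of fused-coronal channel arrays `(z, x, 3)` (or
#'   `fused_coronal` objects), all sharing one spatial size.
#' @param labels list of 0/1 vectors, one per image.
#' @param epochs,lr,batch optimizer settings.
#' @param seed seed for shuffling, dropout and the validation split.
#' @param val_split held-out fraction (default 0.2).
#' @param init_weights optional `list(params =, state =)` to start from.
#' @return The trained `range_model`; its `report` field is a `train_report`
#'   with per-epoch mean loss, final training accuracy, and final
#'   validation loss.
#' @export
train_range_model <- function(model, images, labels, epochs = 8, lr = 1e-3,
                              batch = 8, seed = 1, val_split = 0.2,
                              init_weights = NULL) {
  stopifnot(inherits(model, "range_model"))
  if (length(images) == 0) stop("empty dataset")
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  images <- lapply(images, function(im) {
    if (inherits(im, "fused_coronal")) im$channels else im
  })
  if (!is.null(init_weights)) {
    model$params <- init_weights$params
    model$state <- init_weights$state
  }
  cfg <- model$cfg
  y <- vapply(labels, function(l) resample_vector(as.numeric(l), cfg$out_bins),
              numeric(cfg$out_bins))   # out_bins x n

  n <- length(images)
  opt <- adam_init(model$params)
  loss_hist <- numeric(epochs)
  final_acc <- NA_real_
  with_seed(seed, {
    n_val <- if (n >= 5) max(1L, round(val_split * n)) else 0L
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    for (ep in seq_len(epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      bl <- 0; acc <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch)) {
        ids <- ord[start:min(start + batch - 1, length(ord))]
        x <- stack_images(images[ids])
        yb <- y[, ids, drop = FALSE]
        fw <- range_forward(model, x, train = TRUE)
        model <- fw$model
        loss <- bce_logits_loss(fw$logits, yb)
        grads <- range_backward(model, fw$cache,
                                array(bce_logits_grad(fw$logits, yb),
                                      dim = dim(fw$logits)))
        st <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- st$params; opt <- st$opt
        bl <- bl + loss
        acc <- acc + thresholded_accuracy(nn_sigmoid(fw$logits), yb,
                                          cfg$threshold)
        nb <- nb + 1
      }
      loss_hist[ep] <- bl / nb
      final_acc <- acc / nb
    }
    val_loss <- if (length(val_idx)) {
      xv <- stack_images(images[val_idx])
      fw <- range_forward(model, xv, train = FALSE)
      bce_logits_loss(fw$logits, y[, val_idx, drop = FALSE])
    } else NA_real_
    model$report <- train_report(loss_hist, final_acc, val_loss, seed, epochs,
                                 n_train = length(tr_idx),
                                 n_val = length(val_idx))
  })
  model$trained <- TRUE
  model$epochs_trained <- model$epochs_trained + as.integer(epochs)
  model
}

# Stack equally sized (H, W, C) arrays into an (H, W, C, N) batch.
stack_images <- function(lst) {
  d <- dim(lst[[1]])
  for (im in lst) {
    if (!identical(dim(im), d)) stop("all images in a batch must share one size")
  }
  array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
}

train_report <- function(loss_history, final_train_accuracy, final_val_loss,
                         seed, epochs, n_train, n_val) {
  structure(list(loss_history = loss_history,
                 final_train_accuracy = final_train_accuracy,
                 final_val_loss = final_val_loss, seed = seed,
                 epochs = epochs, n_train = n_train, n_val = n_val),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs, %d train / %d val samples\n",
              x$epochs, x$n_train, x$n_val))
  cat(sprintf("  loss %.4f -> %.4f, final train accuracy %.4f, val loss %s\n",
              x$loss_history[1], x$loss_history[x$epochs],
              x$final_train_accuracy,
              ifelse(is.na(x$final_val_loss), "NA",
                     sprintf("%.4f", x$final_val_loss))))
  invisible(x)
}

#' Element-wise median aggregation of binary range votes
#'
#' Each row of `votes` is one view's binarized per-z presence vector; the
#' aggregate takes the element-wise median (a tie at exactly 0.5, possible
#' only for an even number of views, rounds up to 1) and then keeps the
#' longest contiguous run of ones.
#'
#' @param votes binary matrix, one row per view.
#' @return `list(binary =, interval =)` where `interval` is 1-based
#'   half-open `c(lo, hi)` (empty when `lo == hi`).
#' @export
aggregate_range_votes <- function(votes) {
  votes <- as.matrix(votes)
  med <- as.integer(colMeans(votes) >= 0.5)
  list(binary = med, interval = longest_run_interval(med))
}

# Longest contiguous run of ones, 1-based half-open [lo, hi); ties keep the
# earliest run. All-zero input gives c(1, 1).
longest_run_interval <- function(bin) {
  r <- rle(as.integer(bin))
  ones <- which(r$values == 1)
  if (!length(ones)) return(c(1L, 1L))
  best <- ones[which.max(r$lengths[ones])]
  lo <- if (best == 1) 1L else sum(r$lengths[seq_len(best - 1)]) + 1L
  c(lo, lo + r$lengths[best])
}

#' Predict the vertical muscle range of a volume
#'
#' Extracts `n_views` fused coronal images at rigidly jittered positions,
#' runs each through the trained detector, binarizes the per-bin sigmoid
#' probabilities at the config threshold (after nearest-resampling from
#' `out_bins` back to the isotropic z length), median-aggregates the views
#' element-wise, and keeps the longest contiguous run of ones. The isotropic
#' interval is mapped back to original axial slices with
#' [map_iso_z_to_original()].
#'
#' @param model trained `range_model`.
#' @param iso `iso_volume` of the CT.
#' @param n_views number of jittered views (default 5).
#' @param fractions,max_offset,window fusion settings (see
#'   [extract_fused_coronal()], [sample_fusion_positions()]).
#' @param seed seed for the view jitter.
#' @return A `range_prediction`: per-z `probs` (median across views),
#'   `binary` vector, `iso_interval` and `slice_interval` (both 1-based
#'   half-open), and `empty` flag.
#' @export
predict_range <- function(model, iso, n_views = 5,
                          fractions = c(3, 4, 5) / 8, max_offset = 1 / 16,
                          window = c(-200, 300), seed = 1) {
  stopifnot(inherits(model, "range_model"))
  if (!model$trained) stop("range model has not been trained")
  nz <- dim(iso$voxels)[1]
  triples <- sample_fusion_positions(fractions, n_views, max_offset, seed)
  probs <- matrix(0, n_views, nz)
  for (i in seq_len(n_views)) {
    fused <- extract_fused_coronal(iso, triples[[i]], window)
    x <- array(fused$channels, dim = c(dim(fused$channels), 1L))
    fw <- range_forward(model, x, train = FALSE)
    probs[i, ] <- resample_vector(nn_sigmoid(as.vector(fw$logits)), nz)
  }
  votes <- (probs >= model$cfg$threshold) + 0L
  agg <- aggregate_range_votes(votes)
  iso_int <- agg$interval
  empty <- iso_int[1] == iso_int[2]
  if (empty) {
    warning("range detection produced an empty interval")
    slice_int <- c(1L, 1L)
  } else {
    slice_int <- c(map_iso_z_to_original(iso_int[1], iso),
                   map_iso_z_to_original(iso_int[2] - 1L, iso) + 1L)
  }
  structure(list(probs = apply(probs, 2, stats::median), binary = agg$binary,
                 iso_interval = iso_int, slice_interval = slice_int,
                 empty = empty, n_views = n_views),
            class = "range_prediction")
}

#' @export
print.range_prediction <- function(x, ...) {
  if (x$empty) cat("<range_prediction> empty interval\n")
  else cat(sprintf("<range_prediction> iso z [%d, %d), axial slices [%d, %d)\n",
                   x$iso_interval[1], x$iso_interval[2],
                   x$slice_interval[1], x$slice_interval[2]))
  invisible(x)
}
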