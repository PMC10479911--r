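# Differentiable building blocks for the two networks. All activations are
# R arrays of dim (H, W, C, N). Each *_fwd returns list(y, cache); each
# *_bwd consumes the cache and the upstream gradient. Nothing here touches
# the R RNG except nn_dropout_fwd and the initializers.

nn_he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
}

nn_conv_fwd <- function(x, w, b, stride = 1L, pad = 1L) {
  y <- cpp_conv2d_fwd(x, w, b, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, w = w, stride = stride, pad = pad))
}

nn_conv_bwd <- function(cache, dy) {
  cpp_conv2d_bwd(cache$x, cache$w, dy,
                 as.integer(cache$stride), as.integer(cache$pad))
}

nn_relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
nn_relu_bwd <- function(cache, dy) dy * cache

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization over (H, W, N) per channel. `state` carries running
# moments for eval mode; training uses batch moments and updates the state.
# Per-channel vectors are expanded with rep(..., each = H*W), whose length
# H*W*C recycles exactly once per sample across the (H, W, C, N) array.
bn_sums <- function(x, d) {
  # per-channel sums over (H, W, N): colSums over HW, then over samples
  s <- .colSums(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(s, nrow = d[3]))
}

nn_bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  n_per <- hw * d[4]
  if (train) {
    mu <- bn_sums(x, d) / n_per
    va <- bn_sums(x * x, d) / n_per - mu^2
    va <- pmax(va, 0)
    state$rmean <- (1 - momentum) * state$rmean + momentum * mu
    state$rvar  <- (1 - momentum) * state$rvar + momentum * va
  } else {
    mu <- state$rmean
    va <- state$rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- x * rep(istd, each = hw) - rep(mu * istd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  cache <- if (train) list(xhat = xhat, istd = istd, gamma = gamma,
                           d = d, n_per = n_per) else
    list(istd = istd, gamma = gamma, d = d, eval = TRUE)
  list(y = y, cache = cache, state = state)
}

nn_bn_bwd <- function(cache, dy) {
  d <- cache$d
  C <- d[3]
  hw <- d[1] * d[2]
  if (isTRUE(cache$eval)) {
    return(list(dx = dy * rep(cache$gamma * cache$istd, each = hw),
                dgamma = numeric(C), dbeta = numeric(C)))
  }
  xhat <- cache$xhat
  n <- cache$n_per
  dgamma <- bn_sums(dy * xhat, d)
  dbeta <- bn_sums(dy, d)
  dxhat <- dy * rep(cache$gamma, each = hw)
  s1 <- bn_sums(dxhat, d)
  s2 <- bn_sums(dxhat * xhat, d)
  dx <- (n * dxhat - rep(s1, each = hw) - xhat * rep(s2, each = hw)) *
    rep(cache$istd / n, each = hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 2x2 max pooling, stride 2. Odd extents are edge-replicated up to even so
# inputs of any size pool to ceiling(n/2).
nn_maxpool_fwd <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  Hp <- H + H %% 2L; Wp <- W + W %% 2L
  if (Hp != H || Wp != W) {
    x <- x[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)), , ,
           drop = FALSE]
  }
  io <- seq(1L, Hp, 2L); jo <- seq(1L, Wp, 2L)
  x11 <- x[io, jo, , , drop = FALSE]; x21 <- x[io + 1L, jo, , , drop = FALSE]
  x12 <- x[io, jo + 1L, , , drop = FALSE]; x22 <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  m11 <- x11 == y
  m21 <- (x21 == y) & !m11
  m12 <- (x12 == y) & !m11 & !m21
  m22 <- !(m11 | m21 | m12)
  list(y = y, cache = list(m = list(m11, m21, m12, m22), d = d,
                           Hp = Hp, Wp = Wp))
}

nn_maxpool_bwd <- function(cache, dy) {
  d <- cache$d
  Hp <- cache$Hp; Wp <- cache$Wp
  dxp <- array(0, dim = c(Hp, Wp, d[3], d[4]))
  io <- seq(1L, Hp, 2L); jo <- seq(1L, Wp, 2L)
  m <- cache$m
  dxp[io, jo, , ] <- dy * m[[1]]
  dxp[io + 1L, jo, , ] <- dy * m[[2]]
  dxp[io, jo + 1L, , ] <- dy * m[[3]]
  dxp[io + 1L, jo + 1L, , ] <- dy * m[[4]]
  dx <- dxp[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
  if (Hp != d[1]) dx[d[1], , , ] <- dx[d[1], , , ] + dxp[Hp, seq_len(d[2]), , ]
  if (Wp != d[2]) dx[, d[2], , ] <- dx[, d[2], , ] + dxp[seq_len(d[1]), Wp, , ]
  if (Hp != d[1] && Wp != d[2]) dx[d[1], d[2], , ] <- dx[d[1], d[2], , ] + dxp[Hp, Wp, , ]
  dx
}

# Nearest-neighbour x2 upsampling, optionally cropped to a target (h, w) so
# decoder features line up with skip features when the encoder pooled an odd
# extent.
nn_up2_fwd <- function(x, target_hw = NULL) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  crop <- c(2L * d[1], 2L * d[2])
  if (!is.null(target_hw)) {
    y <- y[seq_len(target_hw[1]), seq_len(target_hw[2]), , , drop = FALSE]
    crop <- as.integer(target_hw)
  }
  list(y = y, cache = list(d = d, crop = crop))
}

nn_up2_bwd <- function(cache, dy) {
  d <- cache$d
  full <- array(0, dim = c(2L * d[1], 2L * d[2], d[3], d[4]))
  full[seq_len(cache$crop[1]), seq_len(cache$crop[2]), , ] <- dy
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  full[io, jo, , , drop = FALSE] + full[io + 1L, jo, , , drop = FALSE] +
    full[io, jo + 1L, , , drop = FALSE] + full[io + 1L, jo + 1L, , , drop = FALSE]
}

# Adaptive average pooling to a fixed (oh, ow) grid; bin edges follow the
# floor/ceiling convention so any input size >= 1 is valid.
nn_adaptive_pool_fwd <- function(x, oh, ow) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- array(0, dim = c(oh, ow, C, N))
  bins <- vector("list", oh * ow)
  for (i in seq_len(oh)) {
    si <- floor((i - 1) * H / oh) + 1L
    ei <- ceiling(i * H / oh)
    for (j in seq_len(ow)) {
      sj <- floor((j - 1) * W / ow) + 1L
      ej <- ceiling(j * W / ow)
      blk <- x[si:ei, sj:ej, , , drop = FALSE]
      y[i, j, , ] <- colMeans(matrix(blk, nrow = (ei - si + 1L) * (ej - sj + 1L)))
      bins[[(j - 1L) * oh + i]] <- c(si, ei, sj, ej)
    }
  }
  list(y = y, cache = list(d = d, oh = oh, ow = ow, bins = bins))
}

nn_adaptive_pool_bwd <- function(cache, dy) {
  d <- cache$d
  dx <- array(0, dim = d)
  oh <- cache$oh; ow <- cache$ow
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      b <- cache$bins[[(j - 1L) * oh + i]]
      hw <- (b[2] - b[1] + 1L) * (b[4] - b[3] + 1L)
      add <- rep(dy[i, j, , ] / hw, each = hw)
      dx[b[1]:b[2], b[3]:b[4], , ] <- dx[b[1]:b[2], b[3]:b[4], , ] + add
    }
  }
  dx
}

nn_linear_fwd <- function(x, w, b) {
  list(y = w %*% x + b, cache = list(x = x, w = w))
}

nn_linear_bwd <- function(cache, dy) {
  list(dx = crossprod(cache$w, dy), dw = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

nn_dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, cache = NULL))
  mask <- array((stats::runif(length(x)) > p) / (1 - p), dim = dim(x))
  list(y = x * mask, cache = mask)
}

nn_dropout_bwd <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# Concatenate two activation tensors along the channel axis.
nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

# Broadcast-multiply a single-channel gate over all channels of x.
nn_gate_mul <- function(x, alpha) {
  C <- dim(x)[3]
  x * alpha[, , rep(1L, C), , drop = FALSE]
}

# Adam with bias correction over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Count of scalar parameters in a flat parameter list.
nn_count_params <- function(params) sum(vapply(params, length, integer(1)))
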