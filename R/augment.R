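#' Paired geometric augmentation of a slice and its mask
#'
#' Applies one random geometric transform — built from any subset of
#' rotation, mirroring, elastic deformation and scaling — identically to an
#' image and its mask. The image is resampled bilinearly, the mask with
#' nearest neighbour so it stays binary. The transform is sampled
#' deterministically from `seed`, so calling twice with the same seed yields
#' identical outputs (and in particular, augmenting the mask alongside the
#' image or independently with the same seed gives the same mask).
#'
#' Sampling ranges: rotation angle uniform in +/- `max_angle` degrees, scale
#' uniform in `1 +/- max_scale`, mirroring a fair coin on the left-right
#' axis, elastic displacement a Gaussian random field (sigma
#' `elastic_sigma` px) scaled to `elastic_alpha` px amplitude.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D binary matrix of the same shape.
#' @param ops character subset of
#'   `c("rotation", "mirroring", "elastic", "scaling")`; empty for identity.
#' @param seed integer seed.
#' @param max_angle,max_scale,elastic_alpha,elastic_sigma transform ranges.
#' @return `list(image =, mask =)`, shapes unchanged.
#' @export
augment_sample <- function(image, mask,
                           ops = c("rotation", "mirroring", "elastic",
                                   "scaling"),
                           seed = 1, max_angle = 15, max_scale = 0.1,
                           elastic_alpha = 4, elastic_sigma = 8) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  bad <- setdiff(ops, c("rotation", "mirroring", "elastic", "scaling"))
  if (length(bad)) stop("unknown augmentation op: ", paste(bad, collapse = ", "))
  H <- nrow(image); W <- ncol(image)

  par <- with_seed(seed, {
    list(angle = if ("rotation" %in% ops)
           stats::runif(1, -max_angle, max_angle) else 0,
         scale = if ("scaling" %in% ops)
           stats::runif(1, 1 - max_scale, 1 + max_scale) else 1,
         mirror = ("mirroring" %in% ops) && stats::runif(1) > 0.5,
         dfield = if ("elastic" %in% ops) {
           # cap the field smoothness so the blur kernel fits the image
           sig <- min(elastic_sigma, (min(H, W) - 2) / 7)
           df <- list(dy = matrix(stats::rnorm(H * W), H, W),
                      dx = matrix(stats::rnorm(H * W), H, W))
           df$dy <- EBImage::gblur(df$dy, sigma = sig)
           df$dx <- EBImage::gblur(df$dx, sigma = sig)
           m <- max(abs(c(df$dy, df$dx)), 1e-9)
           list(dy = df$dy / m * elastic_alpha, dx = df$dx / m * elastic_alpha)
         } else NULL)
  })

  identity_tf <- par$angle == 0 && par$scale == 1 && !par$mirror &&
    is.null(par$dfield)
  if (identity_tf) return(list(image = image, mask = mask))

  # Inverse-map output pixels to source coordinates about the image center.
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  th <- -par$angle * pi / 180          # inverse rotation
  s <- 1 / par$scale                   # inverse scale
  sy <- s * (cos(th) * gy - sin(th) * gx) + cy
  sx <- s * (sin(th) * gy + cos(th) * gx) + cx
  if (par$mirror) sx <- W + 1 - sx
  if (!is.null(par$dfield)) {
    sy <- sy + par$dfield$dy
    sx <- sx + par$dfield$dx
  }
  list(image = warp_image(image, sy, sx, "bilinear"),
       mask = warp_image(mask, sy, sx, "nearest"))
}

# Sample `img` at fractional coordinates (map_y, map_x); out-of-range
# coordinates clamp to the border. Nearest keeps the input's value set.
warp_image <- function(img, map_y, map_x, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  y <- pmin(pmax(map_y, 1), H)
  x <- pmin(pmax(map_x, 1), W)
  if (method == "nearest") {
    out <- img[cbind(as.vector(round(y)), as.vector(round(x)))]
  } else {
    y0 <- pmin(floor(y), H - 1); x0 <- pmin(floor(x), W - 1)
    wy <- as.vector(y - y0); wx <- as.vector(x - x0)
    y0 <- as.vector(y0); x0 <- as.vector(x0)
    v00 <- img[cbind(y0, x0)]; v10 <- img[cbind(y0 + 1, x0)]
    v01 <- img[cbind(y0, x0 + 1)]; v11 <- img[cbind(y0 + 1, x0 + 1)]
    out <- v00 * (1 - wy) * (1 - wx) + v10 * wy * (1 - wx) +
      v01 * (1 - wy) * wx + v11 * wy * wx
  }
  matrix(out, H, W)
}
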