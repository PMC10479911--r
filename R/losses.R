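#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`
#' with `eps = 1e-6`. For hard binary inputs this equals `1 - DSC`; the
#' epsilon smoothing makes an empty prediction of an empty target cost 0
#' rather than being undefined. Used as the segmentation training objective.
#'
#' @param pred probability map (any shape).
#' @param target binary map of the same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    stop("pred and target shapes differ")
  }
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  1 - num / den
}

# Gradient of dice_loss w.r.t. pred.
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  (num - 2 * target * den) / den^2
}

#' Binary cross-entropy with logits
#'
#' Numerically stable mean BCE evaluated directly on logits:
#' `mean(max(l, 0) - l * y + log1p(exp(-|l|)))`. The range-detection model is
#' trained with this objective because each z bin is an independent binary
#' presence decision.
#'
#' @param logits numeric vector/array of raw scores.
#' @param labels binary labels of the same length.
#' @return Scalar mean loss.
#' @export
bce_logits_loss <- function(logits, labels) {
  if (length(logits) != length(labels)) stop("length mismatch")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# Gradient w.r.t. logits: (sigmoid(l) - y) / n.
bce_logits_grad <- function(logits, labels) {
  (nn_sigmoid(logits) - labels) / length(logits)
}

#' Thresholded binary accuracy
#'
#' Fraction of positions where `(probs >= threshold)` matches the binary
#' label; the per-mini-batch accuracy reported during range-model training.
#'
#' @param probs probabilities.
#' @param labels binary labels, same length.
#' @param threshold binarization cutoff (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
thresholded_accuracy <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels)) stop("length mismatch")
  mean((probs >= threshold) == (labels > 0.5))
}
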