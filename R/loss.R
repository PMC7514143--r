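# Class weighting and the improved focal loss.
#
# For a candidate instance with predicted class distribution p and true class
# t, write p_t for the probability assigned to the true class. The training
# objective blends the alpha-weighted focal loss with plain cross-entropy:
#
#   L = -e * alpha_t * (1 - p_t)^gamma * log(p_t) - (1 - e) * log(p_t)
#
# gamma > 0 down-weights easily classified instances ((1-p_t)^gamma is tiny
# when p_t is close to 1) and the per-class alpha, computed from inverse
# class frequency, rebalances the extremely skewed label distribution.

P_FLOOR <- 1e-7

#' Inverse-frequency class weights
#'
#' With total `T = sum(counts)`, class i receives
#' `alpha_i = (T / counts_i) / sum_j (T / counts_j)`: weights sum to 1 and
#' rarer classes get larger weights.
#'
#' @param counts positive per-class instance counts (optionally named).
#' @return Numeric weight vector summing to 1, same names as `counts`.
#' @export
compute_class_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stopf("all class counts must be positive: inverse-frequency weights are undefined for empty classes")
  }
  inv <- 1 / counts
  inv / sum(inv)
}

#' Loss configuration
#'
#' @param gamma focal modulating factor (>= 0; 0 disables modulation, for
#'   ablation).
#' @param e blend weight in `[0, 1]` between the focal term (`e`) and plain
#'   cross-entropy (`1 - e`).
#' @param alpha optional per-class weight vector in `(0, 1]`; when `NULL` the
#'   training routine computes it from the class counts via
#'   [compute_class_weights()].
#' @return An object of class `ddi_loss_config`.
#' @export
loss_config <- function(gamma = 2, e = 0.9, alpha = NULL) {
  stopifnot(gamma >= 0, e >= 0, e <= 1)
  if (!is.null(alpha)) {
    stopifnot(all(alpha > 0), all(alpha <= 1))
  }
  structure(list(gamma = gamma, e = e, alpha = alpha),
            class = "ddi_loss_config")
}

prob_true_class <- function(probs, true_class) {
  if (is.matrix(probs)) {
    stopifnot(length(true_class) == nrow(probs))
    probs[cbind(seq_len(nrow(probs)), true_class)]
  } else {
    probs[true_class]
  }
}

#' Cross-entropy loss
#'
#' `-log(p_t)`, with `p_t` floored at `1e-7` for numerical stability.
#'
#' @param probs probability vector over classes, or a matrix with one row per
#'   instance.
#' @param true_class integer index (or vector) of the true class.
#' @return Loss value(s).
#' @export
cross_entropy <- function(probs, true_class) {
  pt <- pmax(prob_true_class(probs, true_class), P_FLOOR)
  -log(pt)
}

#' Improved focal loss
#'
#' `-e * alpha_t * (1 - p_t)^gamma * log(p_t) - (1 - e) * log(p_t)`.
#' With `e = 0` this is exactly [cross_entropy()]; with `gamma = 0`, `e = 1`
#' it is alpha-weighted cross-entropy.
#'
#' @param probs probability vector over classes, or a matrix with one row per
#'   instance.
#' @param true_class integer index (or vector) of the true class.
#' @param cfg a [loss_config()]; `cfg$alpha` defaults to 1 for every class
#'   when unset.
#' @return Loss value(s); batch losses are reduced by averaging in training.
#' @export
improved_focal_loss <- function(probs, true_class, cfg = loss_config()) {
  pt <- pmax(prob_true_class(probs, true_class), P_FLOOR)
  alpha <- cfg$alpha
  at <- if (is.null(alpha)) 1 else alpha[true_class]
  -cfg$e * at * (1 - pt)^cfg$gamma * log(pt) - (1 - cfg$e) * log(pt)
}

# Gradient of the mean improved focal loss w.r.t. the logits, for a batch.
# probs: B x C softmax output; y: true class indices (1-based).
focal_grad_logits <- function(probs, y, cfg) {
  B <- nrow(probs)
  pt <- pmax(probs[cbind(seq_len(B), y)], P_FLOOR)
  at <- if (is.null(cfg$alpha)) rep(1, B) else cfg$alpha[y]
  g <- cfg$gamma
  mod_term <- if (g == 0) 0 else cfg$e * at * g * (1 - pt)^(g - 1) * log(pt)
  dL_dpt <- mod_term - cfg$e * at * (1 - pt)^g / pt - (1 - cfg$e) / pt
  dL_dpt[probs[cbind(seq_len(B), y)] < P_FLOOR] <- 0  # clamped region
  # d pt / d z_j = pt * (1[j == y] - p_j)
  dz <- -probs * (dL_dpt * pt)
  dz[cbind(seq_len(B), y)] <- dz[cbind(seq_len(B), y)] + dL_dpt * pt
  dz / B
}
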