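# Single-instance views of the network's building blocks. These expose the
# individual operations (context encoding, semantic fusion, instance
# embedding, typical/dilated convolution, max pooling, full forward) on plain
# matrices for inspection and testing; training uses the batched engine in
# network-core.R built from the same primitives.

as_row_list <- function(x) {
  lapply(seq_len(nrow(x)), function(t) x[t, , drop = FALSE])
}

#' Left and right recurrent context of a token sequence
#'
#' For each position i the left context is computed from the embeddings at
#' positions < i only and the right context from positions > i only (in the
#' default `"causal"` mode); each is the concatenation of two directional
#' hidden states and therefore has `2 * hidden` dimensions.
#'
#' @param x numeric matrix, one row per token, `n_w` columns (word
#'   embeddings).
#' @param model a `ddi_model` from [init_ddi_model()].
#' @return List with matrices `left` and `right`, each `nrow(x)` by
#'   `2 * hidden`.
#' @export
context_encode <- function(x, model) {
  if (is.null(dim(x)) || nrow(x) < 1) stopf("empty input sequence")
  stopifnot(ncol(x) == model$config$n_w)
  ctx <- context_forward(model$params, model$config, as_row_list(x), B = 1L)
  list(left = do.call(rbind, ctx$el), right = do.call(rbind, ctx$er))
}

#' Fuse a word embedding with its contextual embeddings
#'
#' Affine map `W_s [left; word; right] + b_s` reducing the
#' `n_l + n_w + n_r`-dimensional concatenation to `n_fused` dimensions.
#'
#' @param word,left,right numeric vectors of the configured dimensions.
#' @param model a `ddi_model` (must be configured with `fusion = TRUE`).
#' @return Numeric vector of length `n_fused`.
#' @export
fuse_semantic <- function(word, left, right, model) {
  cfg <- model$config
  d <- config_dims(cfg)
  if (!cfg$fusion) stopf("model was configured without a fusion layer")
  se <- c(left, word, right)
  if (length(se) != d$n_s) {
    stopf("concatenated input has %d dimensions, expected n_l+n_w+n_r = %d",
          length(se), d$n_s)
  }
  as.vector(se %*% model$params$Ws) + model$params$bs
}

#' Per-token embedding matrix of an encoded instance
#'
#' Concatenates the fused semantic vector of every position with the two
#' position embeddings looked up by its relative distances to the candidate
#' entities, giving `N_E = n_fused + 2 * n_d` channels per token (padding
#' positions use the index-0 embedding rows).
#'
#' @param enc a `ddi_encoded` from [encode_instance()].
#' @param model a `ddi_model`.
#' @return Numeric matrix, `max_len` rows by `N_E` columns.
#' @export
embed_instance <- function(enc, model) {
  cfg <- model$config
  params <- model$params
  if (any(enc$dist1 >= nrow(params$Ep1)) || any(enc$dist2 >= nrow(params$Ep2))) {
    stopf("position index outside the embedding table")
  }
  n <- length(enc$token_ids)
  X <- params$Ew[enc$token_ids + 1L, , drop = FALSE]
  ctx <- context_forward(params, cfg, as_row_list(X), B = 1L)
  bigS <- cbind(do.call(rbind, ctx$el), X, do.call(rbind, ctx$er))
  Es <- if (cfg$fusion) add_bias(bigS %*% params$Ws, params$bs) else bigS
  cbind(Es, params$Ep1[enc$dist1 + 1L, , drop = FALSE],
        params$Ep2[enc$dist2 + 1L, , drop = FALSE])
}

conv_filter_size <- function(E, W) {
  k <- nrow(W) / ncol(E)
  if (k != round(k)) {
    stopf("filter matrix rows (%d) are not a multiple of the input channels (%d)",
          nrow(W), ncol(E))
  }
  as.integer(k)
}

#' Typical (dense-window) convolution over a token embedding sequence
#'
#' Applies each filter to all consecutive windows of `k` tokens followed by
#' ReLU; the output has `n - k + 1` positions.
#'
#' @param E numeric matrix, one row per position, `N_E` channels.
#' @param W filter matrix with `k * ncol(E)` rows (the k stacked window
#'   slices) and one column per filter.
#' @param b bias, one value per filter.
#' @return Matrix of convolved features, `n - k + 1` rows, one column per
#'   filter.
#' @export
typical_conv <- function(E, W, b) {
  dilated_conv(E, W, b, d = 1L)
}

#' Dilated convolution over a token embedding sequence
#'
#' Like [typical_conv()] but the k filter taps are spaced `d` positions
#' apart, covering a receptive span of `(k-1)*d + 1` consecutive positions;
#' the output has `n - (k-1)*d` positions. With `d = 1` the operation is
#' identical to the typical convolution.
#'
#' @inheritParams typical_conv
#' @param d dilation width (>= 1).
#' @return Matrix of convolved features, `n - (k-1)*d` rows.
#' @export
dilated_conv <- function(E, W, b, d = 2L) {
  stopifnot(d >= 1)
  k <- conv_filter_size(E, W)
  n <- nrow(E)
  L <- conv_out_len(n, k, as.integer(d))
  if (L < 1) {
    stopf("sequence of length %d too short for filter size %d with dilation %d (needs %d)",
          n, k, d, (k - 1) * d + 1)
  }
  out <- matrix(0, L, ncol(W))
  for (i in seq_len(L)) {
    win <- as.vector(t(E[i + (0:(k - 1)) * d, , drop = FALSE]))
    out[i, ] <- pmax(win %*% W + b, 0)
  }
  out
}

#' Sliding max pooling
#'
#' Takes the per-filter maximum over windows of `w` positions with stride
#' `w`; a shorter final window is pooled as-is. With `w = nrow(F)` this is
#' global max pooling.
#'
#' @param F feature matrix, one row per position, one column per filter.
#' @param w pooling window (and stride).
#' @return Pooled feature matrix with `ceiling(nrow(F) / w)` rows.
#' @export
max_pool <- function(F, w) {
  F <- as.matrix(F)
  L <- nrow(F)
  if (L < w) stopf("feature sequence of length %d shorter than pool window %d", L, w)
  starts <- seq.int(1L, L, by = w)
  out <- t(vapply(starts, function(s) {
    apply(F[s:min(s + w - 1L, L), , drop = FALSE], 2, max)
  }, numeric(ncol(F))))
  matrix(out, nrow = length(starts), ncol = ncol(F))
}

#' Class probabilities for one encoded instance
#'
#' Runs the full network: instance embedding, the two convolution branches
#' (each two conv + max-pool blocks and a global max pool), concatenation,
#' dropout (training mode only) and the softmax output layer.
#'
#' @param model a `ddi_model`.
#' @param enc a `ddi_encoded`.
#' @param train apply dropout (stochastic); with `FALSE` the forward pass is
#'   deterministic.
#' @return Named probability vector over `model$config$classes`, summing
#'   to 1.
#' @export
ddi_forward <- function(model, enc, train = FALSE) {
  out <- net_forward(model, stack_instances(list(enc)), train = train)
  stats::setNames(as.vector(out$probs), model$config$classes)
}

#' Predict DDI labels
#'
#' @param object a trained `ddi_model`.
#' @param instances list of `ddi_instance` (raw candidates) or `ddi_encoded`
#'   objects.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param batch_size instances per forward batch.
#' @param ... unused.
#' @return Character vector of predicted labels, or a probability matrix with
#'   one row per instance.
#' @export
predict.ddi_model <- function(object, instances, type = c("class", "prob"),
                              batch_size = 64L, ...) {
  type <- match.arg(type)
  if (length(instances) == 0) {
    return(if (type == "class") character(0) else
      matrix(0, 0, object$config$n_classes))
  }
  if (inherits(instances[[1]], "ddi_instance")) {
    instances <- encode_instances(instances, object$vocab,
                                  object$config$max_len)
  }
  probs <- do.call(rbind, lapply(split(seq_along(instances),
                                       ceiling(seq_along(instances) / batch_size)),
                                 function(idx) {
    net_forward(object, stack_instances(instances[idx]), train = FALSE)$probs
  }))
  colnames(probs) <- object$config$classes
  if (type == "prob") probs else
    object$config$classes[max.col(probs, ties.method = "first")]
}
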