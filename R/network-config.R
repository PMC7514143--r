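# Architecture configuration and parameter initialization for the recurrent
# hybrid convolutional network.
#
# Per-token representation: a word embedding (n_w) is combined with left and
# right context vectors produced by recurrent cells (each 2*hidden wide) and
# fused through a fully connected layer down to n_fused dimensions; two
# relative-position embeddings (n_d each, one per candidate entity) are
# concatenated, giving N_E = n_fused + 2*n_d channels per token. The sentence
# is then encoded by two parallel convolution branches — typical (dense
# windows) and dilated (taps d positions apart) — each with two
# (convolution -> max-pool) blocks and a final global max pool; the pooled
# features are concatenated, passed through dropout and a softmax layer over
# the five classes.

#' Network configuration
#'
#' Defaults follow the reference setting of the method: 200-dimensional word
#' embeddings, 100 recurrent hidden units per direction (so the left/right
#' context vectors are 200-dimensional each), 15-dimensional position
#' embeddings, filter sizes 3 and 5 for both convolution branches, dilation
#' 2, dropout 0.5 and a maximum sentence length of 150 tokens.
#'
#' @param n_w word-embedding dimension.
#' @param hidden recurrent units per direction; the left/right context
#'   embeddings each have `2 * hidden` dimensions.
#' @param n_fused output dimension of the semantic fusion layer.
#' @param n_d position-embedding dimension (per entity).
#' @param filter_sizes typical-convolution filter sizes.
#' @param dilated_sizes dilated-convolution filter sizes.
#' @param dilation dilation width d (taps are d positions apart).
#' @param n_filters filters per branch and filter size.
#' @param pool_w max-pooling window (and stride).
#' @param dropout dropout probability on the sentence vector (training only).
#' @param max_len maximum sentence length in tokens.
#' @param classes class labels; the softmax output has one unit per class.
#' @param cell_type `"lstm"` (default) or `"rnn"` (simple tanh recurrence).
#' @param context_mode `"causal"` (default): the left context of a token is
#'   computed by two independent recurrences over the preceding tokens only,
#'   and symmetrically for the right context; `"bilstm"`: a single
#'   bidirectional recurrence over the whole sentence, with the context of a
#'   token taken from its neighbours' hidden states (not causal).
#' @param fusion apply the semantic fusion layer; with `FALSE` (ablation) the
#'   raw `[left; word; right]` concatenation is used directly.
#' @return An object of class `ddi_net_config`.
#' @export
network_config <- function(n_w = 200L, hidden = 100L, n_fused = 200L,
                           n_d = 15L, filter_sizes = c(3L, 5L),
                           dilated_sizes = c(3L, 5L), dilation = 2L,
                           n_filters = 100L, pool_w = 2L, dropout = 0.5,
                           max_len = 150L, classes = ddi_classes(),
                           cell_type = c("lstm", "rnn"),
                           context_mode = c("causal", "bilstm"),
                           fusion = TRUE) {
  cell_type <- match.arg(cell_type)
  context_mode <- match.arg(context_mode)
  stopifnot(n_w >= 1, hidden >= 1, n_fused >= 1, n_d >= 1,
            all(filter_sizes >= 1), all(dilated_sizes >= 1), dilation >= 1,
            n_filters >= 1, pool_w >= 1, dropout >= 0, dropout < 1,
            max_len >= 1, length(classes) >= 2)
  cfg <- structure(list(
    n_w = as.integer(n_w), hidden = as.integer(hidden),
    n_fused = as.integer(n_fused), n_d = as.integer(n_d),
    filter_sizes = as.integer(filter_sizes),
    dilated_sizes = as.integer(dilated_sizes),
    dilation = as.integer(dilation), n_filters = as.integer(n_filters),
    pool_w = as.integer(pool_w), dropout = dropout,
    max_len = as.integer(max_len), classes = classes,
    n_classes = length(classes), cell_type = cell_type,
    context_mode = context_mode, fusion = fusion
  ), class = "ddi_net_config")
  d <- config_dims(cfg)
  for (tw in d$towers) {
    if (cfg$max_len - (tw$k - 1L) * tw$d < 1L) {
      stopf("max_len %d too short for filter size %d with dilation %d",
            cfg$max_len, tw$k, tw$d)
    }
  }
  cfg
}

# Derived dimensions and the tower (branch x filter-size) layout.
config_dims <- function(cfg) {
  n_l <- 2L * cfg$hidden
  n_s <- n_l + cfg$n_w + n_l
  n_sem <- if (cfg$fusion) cfg$n_fused else n_s
  n_e <- n_sem + 2L * cfg$n_d
  towers <- c(
    lapply(cfg$filter_sizes, function(k) list(name = paste0("t", k),
                                              k = k, d = 1L)),
    lapply(cfg$dilated_sizes, function(k) list(name = paste0("d", k),
                                               k = k, d = cfg$dilation))
  )
  names(towers) <- vapply(towers, `[[`, "", "name")
  list(n_l = n_l, n_r = n_l, n_s = n_s, n_sem = n_sem, n_e = n_e,
       towers = towers, s_dim = length(towers) * cfg$n_filters,
       pos_rows = 2L * cfg$max_len)
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_cell <- function(nin, hidden, cell_type) {
  if (cell_type == "lstm") {
    b <- numeric(4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
    list(Wx = glorot(nin, 4L * hidden), Wh = glorot(hidden, 4L * hidden), b = b)
  } else {
    list(Wx = glorot(nin, hidden), Wh = glorot(hidden, hidden),
         b = numeric(hidden))
  }
}

#' Initialize a model
#'
#' Creates the full trainable parameter set: the word-embedding table (rows
#' indexed by token id + 1, row 1 being the padding id), the two
#' position-embedding tables, the recurrent context cells, the fusion layer,
#' the convolution filters of every tower and the softmax output layer.
#' Embedding tables are drawn uniformly from `[-0.05, 0.05]`; weight matrices
#' use Glorot-uniform initialization. Tokens present in `embeddings` are
#' initialized from it; all others (out-of-vocabulary) keep their random
#' draw.
#'
#' @param config a [network_config()].
#' @param vocab a `ddi_vocab` from [build_vocab()].
#' @param embeddings optional pretrained word-embedding matrix with tokens as
#'   row names (see [read_word2vec()]); its column count must equal
#'   `config$n_w`.
#' @param seed RNG seed for the initialization draw.
#' @return An object of class `ddi_model` with elements `config`, `params`,
#'   `vocab`.
#' @export
init_ddi_model <- function(config, vocab, embeddings = NULL, seed = 1L) {
  d <- config_dims(config)
  with_seed(seed, {
    params <- list()
    params$Ew <- matrix(stats::runif(vocab$size * config$n_w, -0.05, 0.05),
                        vocab$size, config$n_w)
    params$Ew[1, ] <- 0  # padding row
    if (!is.null(embeddings)) {
      if (ncol(embeddings) != config$n_w) {
        stopf("pretrained embeddings have %d dimensions, config wants %d",
              ncol(embeddings), config$n_w)
      }
      hit <- intersect(rownames(embeddings), vocab$tokens)
      params$Ew[vocab$ids[hit] + 1L, ] <- embeddings[hit, , drop = FALSE]
    }
    params$Ep1 <- matrix(stats::runif(d$pos_rows * config$n_d, -0.05, 0.05),
                         d$pos_rows, config$n_d)
    params$Ep2 <- matrix(stats::runif(d$pos_rows * config$n_d, -0.05, 0.05),
                         d$pos_rows, config$n_d)
    params$Ep1[1, ] <- 0
    params$Ep2[1, ] <- 0
    for (nm in context_cell_names(config)) {
      cell <- init_cell(config$n_w, config$hidden, config$cell_type)
      params[[paste0(nm, "_Wx")]] <- cell$Wx
      params[[paste0(nm, "_Wh")]] <- cell$Wh
      params[[paste0(nm, "_b")]] <- cell$b
    }
    if (config$fusion) {
      params$Ws <- glorot(d$n_s, config$n_fused)
      params$bs <- numeric(config$n_fused)
    }
    for (tw in d$towers) {
      params[[paste0(tw$name, "_W1")]] <- glorot(tw$k * d$n_e, config$n_filters)
      params[[paste0(tw$name, "_b1")]] <- numeric(config$n_filters)
      params[[paste0(tw$name, "_W2")]] <- glorot(tw$k * config$n_filters,
                                                 config$n_filters)
      params[[paste0(tw$name, "_b2")]] <- numeric(config$n_filters)
    }
    params$Wo <- glorot(d$s_dim, config$n_classes)
    params$bo <- numeric(config$n_classes)
    structure(list(config = config, params = params, vocab = vocab),
              class = "ddi_model")
  })
}

context_cell_names <- function(config) {
  if (config$context_mode == "causal") c("cl1", "cl2", "cr1", "cr2")
  else c("cf", "cb")
}

#' @export
print.ddi_model <- function(x, ...) {
  d <- config_dims(x$config)
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<ddi_model> %s cells (%s context), N_E=%d, towers: %s, ",
                     "%d classes, %d parameters\n"),
              x$config$cell_type, x$config$context_mode, d$n_e,
              paste(names(d$towers), collapse = " "), x$config$n_classes, np))
  invisible(x)
}
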