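# Mini-batch Adam training of the network under the improved focal loss.

#' Training configuration
#'
#' @param batch_size instances per mini-batch.
#' @param lr Adam learning rate.
#' @param max_epochs maximum number of passes over the training set.
#' @param patience early-stopping patience, in epochs without improvement of
#'   the validation micro-F (ignored when no dev set is supplied).
#' @param seed RNG seed controlling initialization, shuffling and dropout;
#'   training is deterministic given the seed.
#' @param verbose print one line per epoch.
#' @return An object of class `ddi_train_config`.
#' @export
train_config <- function(batch_size = 32L, lr = 1e-3, max_epochs = 50L,
                         patience = 5L, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1, lr > 0, max_epochs >= 1, patience >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "ddi_train_config")
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

dev_micro_f <- function(model, enc, gold) {
  pred <- predict(model, enc)
  m <- suppressWarnings(micro_prf(ddi_confusion(gold, pred,
                                                model$config$classes)))
  m$micro$f
}

#' Train a DDI classification model
#'
#' Encodes the instances, computes the per-class focal-loss weights from the
#' training-set class counts (unless `loss$alpha` is preset), and optimizes
#' the mean improved focal loss with mini-batch Adam. When a dev set is
#' given, the epoch with the best dev micro-F (over the four positive
#' classes) is kept and training stops early after `patience` epochs without
#' improvement.
#'
#' @param train_instances list of `ddi_instance` objects (training set; every
#'   class must be present, otherwise the inverse-frequency weights are
#'   undefined).
#' @param dev_instances optional list of `ddi_instance` objects for
#'   validation.
#' @param config a [network_config()].
#' @param loss a [loss_config()].
#' @param train a [train_config()].
#' @param vocab optional prebuilt `ddi_vocab`; built from the training tokens
#'   when `NULL`.
#' @param embeddings optional pretrained word embeddings (see
#'   [read_word2vec()]).
#' @return A trained `ddi_model` with extra elements `history` (data frame:
#'   epoch, train_loss, dev_micro_f), `best_epoch`, `loss` (the loss config
#'   including the computed alpha) and `class_counts`.
#' @export
train_ddi_model <- function(train_instances, dev_instances = NULL,
                            config = network_config(), loss = loss_config(),
                            train = train_config(), vocab = NULL,
                            embeddings = NULL) {
  stopifnot(length(train_instances) >= 1)
  labels <- vapply(train_instances, `[[`, "", "label")
  counts <- table(factor(labels, levels = config$classes))
  if (any(counts == 0)) {
    stopf("class(es) %s missing from the training set; per-class weights are undefined",
          paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (is.null(loss$alpha)) {
    loss$alpha <- stats::setNames(compute_class_weights(as.integer(counts)),
                                  config$classes)
  }
  if (is.null(vocab)) vocab <- build_vocab(train_instances)
  enc_train <- encode_instances(train_instances, vocab, config$max_len)
  enc_dev <- if (!is.null(dev_instances)) {
    encode_instances(dev_instances, vocab, config$max_len)
  }
  gold_dev <- if (!is.null(dev_instances)) {
    vapply(dev_instances, `[[`, "", "label")
  }
  model <- init_ddi_model(config, vocab, embeddings = embeddings,
                          seed = train$seed)
  st <- adam_init(model$params)
  ntr <- length(enc_train)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        dev_micro_f = numeric(0))
  best <- list(f = -Inf, params = model$params, epoch = 0L)
  stall <- 0L
  with_seed(train$seed + 1L, {
    for (epoch in seq_len(train$max_epochs)) {
      idx <- sample.int(ntr)
      batches <- split(idx, ceiling(seq_along(idx) / train$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        batch <- stack_instances(enc_train[batches[[bi]]])
        lg <- net_loss_grads(model, batch, loss, train = TRUE)
        losses[bi] <- lg$loss
        upd <- adam_step(model$params, lg$grads, st, train$lr)
        model$params <- upd$params
        st <- upd$state
      }
      devf <- if (!is.null(enc_dev)) dev_micro_f(model, enc_dev, gold_dev) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           dev_micro_f = devf))
      if (train$verbose) {
        message(sprintf("epoch %d  train loss %.4f  dev micro-F %s", epoch,
                        mean(losses),
                        if (is.na(devf)) "-" else sprintf("%.4f", devf)))
      }
      if (!is.null(enc_dev)) {
        if (devf > best$f) {
          best <- list(f = devf, params = model$params, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= train$patience) break
        }
      } else {
        best <- list(f = NA_real_, params = model$params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$loss <- loss
  model$class_counts <- stats::setNames(as.integer(counts), config$classes)
  model
}

#' Write a training history as CSV
#'
#' @param model a trained `ddi_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
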