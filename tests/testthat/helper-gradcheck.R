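# Numerical-vs-analytic gradient agreement for the full network + loss, on a
# small configuration where central differences are cheap.

grad_check_worst <- function(cell_type, context_mode, fusion = TRUE,
                             seed = 42, per_param = 25L) {
  cfg <- network_config(n_w = 5, hidden = 3, n_fused = 6, n_d = 2,
                        filter_sizes = 2L, dilated_sizes = 2L, dilation = 2L,
                        n_filters = 3L, pool_w = 2L, dropout = 0,
                        max_len = 8L, cell_type = cell_type,
                        context_mode = context_mode, fusion = fusion)
  vocab <- tiny_vocab()
  model <- init_ddi_model(cfg, vocab, seed = seed)
  set.seed(seed + 1)
  batch <- stack_instances(list(random_encoded(cfg, vocab),
                                random_encoded(cfg, vocab)))
  lc <- loss_config(gamma = 2, e = 0.9,
                    alpha = c(0.15, 0.08, 0.10, 0.67, 0.01))
  lg <- ddinet:::net_loss_grads(model, batch, lc, train = FALSE)
  loss_fn <- function(params) {
    m <- model; m$params <- params
    fw <- ddinet:::net_forward(m, batch, train = FALSE)
    mean(improved_focal_loss(fw$probs, batch$label, lc))
  }
  h <- 1e-5
  worst <- 0
  for (nm in names(model$params)) {
    idx <- seq_along(model$params[[nm]])
    if (length(idx) > per_param) idx <- sample(idx, per_param)
    for (i in idx) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      ana <- lg$grads[[nm]][i]
      if (abs(num) + abs(ana) > 1e-8) {
        worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
      }
    }
  }
  worst
}
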