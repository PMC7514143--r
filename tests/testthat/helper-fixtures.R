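# Shared fixtures, built in code.

# The worked drug-blinding example sentence: three drug mentions, two
# annotated Mechanism pairs, one same-name Negative pair.
table1_sentence <- function() {
  txt <- "DIAMOX modifies phenytoin metabolism with increased serum levels of phenytoin."
  ddi_sentence(
    "DDI-DrugBank.d368.s0", txt,
    entities = list(ddi_entity("e0", c(0, 5), "DIAMOX"),
                    ddi_entity("e1", c(16, 24), "phenytoin"),
                    ddi_entity("e2", c(68, 76), "phenytoin")),
    pairs = list(ddi_pair("p0", "e0", "e1", "Mechanism"),
                 ddi_pair("p1", "e0", "e2", "Mechanism"),
                 ddi_pair("p2", "e1", "e2", "Negative")))
}

# Benchmark test-set confusion matrix used in the worked evaluation example
# (composite cells summed; rows = true, cols = predicted).
benchmark_confusion <- function() {
  matrix(as.integer(c(178, 5, 3, 2, 33,
                      2, 269, 9, 0, 80,
                      7, 4, 232, 0, 59,
                      0, 36, 2, 43, 15,
                      34, 58, 45, 5, 4595)),
         nrow = 5, byrow = TRUE,
         dimnames = list(true = ddi_classes(), predicted = ddi_classes()))
}

# Filtered training-set class counts of the benchmark corpus.
benchmark_train_counts <- c(Advice = 822, Effect = 1669, Mechanism = 1319,
                            Int = 188, Negative = 19012)

tiny_config <- function(...) {
  network_config(n_w = 5L, hidden = 3L, n_fused = 6L, n_d = 2L,
                 filter_sizes = 2L, dilated_sizes = 2L, dilation = 2L,
                 n_filters = 3L, pool_w = 2L, dropout = 0, max_len = 8L, ...)
}

tiny_vocab <- function() build_vocab(list(letters[1:6]))

random_encoded <- function(cfg, vocab) {
  n <- cfg$max_len
  structure(list(token_ids = sample(0:(vocab$size - 1L), n, replace = TRUE),
                 dist1 = sample(seq_len(2L * n - 1L), n, replace = TRUE),
                 dist2 = sample(seq_len(2L * n - 1L), n, replace = TRUE),
                 length = n, label = "Effect",
                 label_id = sample.int(cfg$n_classes, 1), flagged = FALSE),
            class = "ddi_encoded")
}

# Independent brute-force P/R/F from raw label vectors (positive classes
# pooled), used as an oracle against the confusion-matrix route.
brute_micro_prf <- function(gold, pred) {
  pos <- setdiff(ddi_classes(), "Negative")
  tp <- sum(gold == pred & gold %in% pos)
  fp <- sum(gold != pred & pred %in% pos)
  fn <- sum(gold != pred & gold %in% pos)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f = f)
}
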