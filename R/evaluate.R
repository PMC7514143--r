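# Confusion matrix and the micro-averaged / per-type precision, recall and
# F-score of the DDI task. Micro aggregation pools TP/FP/FN over the four
# positive classes only: the Negative (no-interaction) class contributes via
# its confusions with positive classes but is not itself scored, which is the
# task's standard convention.

#' Confusion matrix over the five DDI classes
#'
#' @param gold,pred character (or factor) label vectors of equal length.
#' @param classes class order; defaults to [ddi_classes()].
#' @return A `classes x classes` integer matrix of class `ddi_confusion`,
#'   rows = true label, columns = predicted label.
#' @export
ddi_confusion <- function(gold, pred, classes = ddi_classes()) {
  if (length(gold) != length(pred)) {
    stopf("gold and predicted label vectors differ in length (%d vs %d)",
          length(gold), length(pred))
  }
  g <- factor(as.character(gold), levels = classes)
  p <- factor(as.character(pred), levels = classes)
  if (anyNA(g) || anyNA(p)) stopf("labels outside the class set")
  m <- table(g, p)
  structure(matrix(as.integer(m), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes)),
            class = c("ddi_confusion", "matrix"))
}

as_confusion <- function(cm, classes = ddi_classes()) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == length(classes), ncol(cm) == length(classes),
            all(cm >= 0))
  dimnames(cm) <- list(true = classes, predicted = classes)
  cm
}

safe_div <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0)) {
    warning(sprintf("zero denominator in %s; metric defined as 0", what),
            call. = FALSE)
  }
  out
}

#' Micro-averaged and per-type precision / recall / F-score
#'
#' Pools true positives (positive-class diagonal), false positives
#' (off-diagonal mass in positive-class columns) and false negatives
#' (off-diagonal mass in positive-class rows) over the four positive classes,
#' then `micro-P = TP/(TP+FP)`, `micro-R = TP/(TP+FN)` and micro-F their
#' harmonic mean. Per-type P/R/F are also reported for each positive class.
#'
#' @param cm a confusion matrix from [ddi_confusion()] (or any 5x5 count
#'   matrix in the canonical class order).
#' @return An object of class `ddi_metrics`: list with `micro`
#'   (`precision`, `recall`, `f`), `per_type` (data frame), and pooled counts
#'   `tp`, `fp`, `fn`. All metrics are proportions in `[0, 1]`.
#' @export
micro_prf <- function(cm) {
  cm <- as_confusion(cm)
  pos <- ddi_positive_classes()
  tp_i <- diag(cm)[pos]
  col_i <- colSums(cm)[pos]
  row_i <- rowSums(cm)[pos]
  tp <- sum(tp_i)
  fp <- sum(col_i - tp_i)
  fn <- sum(row_i - tp_i)
  p <- safe_div(tp, tp + fp, "micro precision")
  r <- safe_div(tp, tp + fn, "micro recall")
  f <- safe_div(2 * p * r, p + r, "micro F")
  pp <- safe_div(tp_i, col_i, "per-type precision")
  rr <- safe_div(tp_i, row_i, "per-type recall")
  ff <- safe_div(2 * pp * rr, pp + rr, "per-type F")
  structure(list(
    micro = list(precision = p, recall = r, f = f),
    per_type = data.frame(type = pos, precision = unname(pp),
                          recall = unname(rr), f = unname(ff),
                          stringsAsFactors = FALSE),
    tp = tp, fp = fp, fn = fn
  ), class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, ...) {
  pct <- function(v) sprintf("%.2f", round_half_up(100 * v, 2))
  cat("DDI evaluation (micro over positive classes)\n")
  cat(sprintf("  micro-P %s%%  micro-R %s%%  micro-F %s%%  (TP %d, FP %d, FN %d)\n",
              pct(x$micro$precision), pct(x$micro$recall), pct(x$micro$f),
              x$tp, x$fp, x$fn))
  for (i in seq_len(nrow(x$per_type))) {
    cat(sprintf("  %-9s P %s%%  R %s%%  F %s%%\n", x$per_type$type[i],
                pct(x$per_type$precision[i]), pct(x$per_type$recall[i]),
                pct(x$per_type$f[i])))
  }
  invisible(x)
}

#' Error breakdown of a confusion matrix
#'
#' Decomposes the misclassified mass into (a) positive instances predicted
#' Negative, (b) Negative instances predicted positive, and (c) confusions
#' between two different positive classes.
#'
#' @param cm a confusion matrix (see [micro_prf()]).
#' @return Named list with `pos_as_negative`, `neg_as_positive`,
#'   `pos_confused`, `total` (their sum, i.e. all off-diagonal mass).
#' @export
error_breakdown <- function(cm) {
  cm <- as_confusion(cm)
  pos <- ddi_positive_classes()
  pos_as_neg <- sum(cm[pos, "Negative"])
  neg_as_pos <- sum(cm["Negative", pos])
  pp <- cm[pos, pos]
  pos_conf <- sum(pp) - sum(diag(pp))
  list(pos_as_negative = pos_as_neg,
       neg_as_positive = neg_as_pos,
       pos_confused = pos_conf,
       total = pos_as_neg + neg_as_pos + pos_conf)
}

#' Write a metrics report as JSON
#'
#' @param metrics a `ddi_metrics` from [micro_prf()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(list(
    micro = metrics$micro,
    per_type = metrics$per_type,
    counts = list(tp = metrics$tp, fp = metrics$fp, fn = metrics$fn)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a confusion matrix as TSV
#'
#' @param cm confusion matrix.
#' @param path file path.
#' @return `write_confusion_tsv` returns `path` invisibly;
#'   `read_confusion_tsv` returns the matrix.
#' @export
write_confusion_tsv <- function(cm, path) {
  cm <- as_confusion(cm)
  utils::write.table(cm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_confusion_tsv
#' @export
read_confusion_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  as_confusion(m)
}

#' Negative-to-positive imbalance ratio
#'
#' The "1 : x" class-imbalance ratio of a corpus, reported to two decimals.
#'
#' @param n_negative,n_positive instance counts.
#' @return `n_negative / n_positive` rounded half-up to 2 decimals.
#' @export
imbalance_ratio <- function(n_negative, n_positive) {
  round_half_up(n_negative / n_positive, 2)
}
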