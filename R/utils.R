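#' @keywords internal
"_PACKAGE"

#' The five DDI classes in canonical order
#'
#' Returns the label set used throughout the package: the four positive
#' interaction types followed by the Negative (no-interaction) class. The
#' order is the one used for confusion matrices and per-type reports.
#'
#' @return Character vector of length 5:
#'   `c("Advice", "Effect", "Mechanism", "Int", "Negative")`.
#' @export
ddi_classes <- function() {
  c("Advice", "Effect", "Mechanism", "Int", "Negative")
}

ddi_positive_classes <- function() {
  setdiff(ddi_classes(), "Negative")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Base R rounds half to even; reported percentages in this package follow the
#' usual round-half-up presentation convention instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Sum rows of `d` into an `nout`-row matrix by 1-based row index `idx`.
scatter_rows <- function(d, idx, nout) {
  out <- matrix(0, nout, ncol(d))
  s <- rowsum(d, group = idx, reorder = FALSE)
  out[as.integer(rownames(s)), ] <- s
  out
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
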