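# Pretrained word embeddings in the word2vec text format: a header line
# "vocab_size dim" followed by one "token v1 v2 ... vD" line per token.
# Pretrained vectors are optional throughout the package; tokens without a
# pretrained vector keep their seeded random initialization.

#' Read word embeddings in word2vec text format
#'
#' @param path file path.
#' @param tokens optional character vector; when given, only these tokens are
#'   kept (saves memory for large embedding files).
#' @return Numeric matrix with tokens as row names.
#' @export
read_word2vec <- function(path, tokens = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stopf("empty embedding file '%s'", path)
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stopf("'%s' has no 'vocab_size dim' header line", path)
  }
  nv <- as.integer(hdr[1]); dim <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != nv) {
    stopf("'%s' announces %d vectors but contains %d", path, nv, length(body))
  }
  parts <- strsplit(body, "[[:space:]]+")
  toks <- vapply(parts, `[[`, "", 1)
  if (!is.null(tokens)) {
    sel <- toks %in% tokens
    parts <- parts[sel]
    toks <- toks[sel]
  }
  if (length(parts) == 0) {
    return(matrix(0, 0, dim, dimnames = list(character(0), NULL)))
  }
  m <- t(vapply(parts, function(p) {
    v <- as.numeric(p[-1])
    if (length(v) != dim) stopf("embedding row for '%s' has %d values, expected %d",
                                p[1], length(v), dim)
    v
  }, numeric(dim)))
  rownames(m) <- toks
  m
}

#' Write word embeddings in word2vec text format
#'
#' @param m numeric matrix with tokens as row names.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_word2vec <- function(m, path) {
  stopifnot(!is.null(rownames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i],
                     paste(format(m[i, ], scientific = FALSE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}
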