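# Drug blinding, tokenization, negative-instance filtering and fixed-length
# integer encoding with relative-position features.

#' Blind a candidate drug pair in a sentence
#'
#' Replaces the surface text of the two candidate entities with `DRUG1` and
#' `DRUG2` and every other entity mention with `DRUG0`, so the classifier
#' generalizes across drug names. Replacement is offset-based, applied from
#' the largest offset backwards so earlier offsets stay valid. For a
#' discontinuous mention only the first span is replaced; the remaining spans
#' are deleted.
#'
#' @param sentence a [ddi_sentence()].
#' @param e1_id,e2_id entity ids of the candidate pair.
#' @return The blinded sentence text.
#' @export
blind <- function(sentence, e1_id, e2_id) {
  validate_sentence(sentence)
  ids <- vapply(sentence$entities, `[[`, "", "id")
  if (!all(c(e1_id, e2_id) %in% ids)) {
    stopf("sentence '%s': pair entities not found", sentence$id)
  }
  edits <- list()  # (start, end, replacement), 0-based inclusive
  for (e in sentence$entities) {
    sym <- if (e$id == e1_id) "DRUG1" else if (e$id == e2_id) "DRUG2" else "DRUG0"
    sp <- e$char_spans
    edits[[length(edits) + 1L]] <- c(sp[1, 1], sp[1, 2], sym)
    if (nrow(sp) > 1) {
      for (r in 2:nrow(sp)) {
        edits[[length(edits) + 1L]] <- c(sp[r, 1], sp[r, 2], "")
      }
    }
  }
  starts <- as.integer(vapply(edits, `[[`, "", 1))
  ends <- as.integer(vapply(edits, `[[`, "", 2))
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-length(o)])) {
    stopf("sentence '%s': overlapping entity spans, cannot blind", sentence$id)
  }
  text <- sentence$text
  for (i in order(starts, decreasing = TRUE)) {
    text <- paste0(substr(text, 1, starts[i]),       # chars before span
                   edits[[i]][3],
                   substr(text, ends[i] + 2, nchar(text)))
  }
  text
}

#' Tokenize DDI text
#'
#' Deterministic rule-based tokenization: splits on whitespace, separates
#' every punctuation character into a standalone token, lowercases all tokens
#' except the blinding symbols `DRUG0`/`DRUG1`/`DRUG2`, and normalizes each
#' digit to `"0"` so numeric literals collapse onto a shared shape token.
#'
#' @param text input string.
#' @return Character vector of tokens (empty for empty input).
#' @export
tokenize_ddi <- function(text) {
  if (is.null(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0) return(character(0))
  blinded <- grepl("^DRUG[012]$", toks)
  toks[!blinded] <- gsub("[0-9]", "0", tolower(toks[!blinded]))
  toks
}

#' Build candidate instances for a sentence
#'
#' One blinded, tokenized classification instance per candidate drug pair.
#' For annotated corpora the pairs listed in the sentence are trusted as-is;
#' with `use_annotated_pairs = FALSE` (synthetic or validation mode) all
#' C(m,2) pairs are enumerated via [enumerate_candidates()].
#'
#' @param sentence a [ddi_sentence()].
#' @param use_annotated_pairs use the sentence's own pair list when present.
#' @return List of `ddi_instance` objects with fields `instance_id`,
#'   `sentence_id`, `text` (blinded), `tokens`, `e1_index`, `e2_index`,
#'   `label`, the original mention texts/spans and the source sentence text.
#' @export
candidate_instances <- function(sentence, use_annotated_pairs = TRUE) {
  validate_sentence(sentence)
  if (use_annotated_pairs && length(sentence$pairs) > 0) {
    pairs <- data.frame(
      id = vapply(sentence$pairs, `[[`, "", "id"),
      e1 = vapply(sentence$pairs, `[[`, "", "e1_id"),
      e2 = vapply(sentence$pairs, `[[`, "", "e2_id"),
      label = vapply(sentence$pairs, `[[`, "", "label"),
      stringsAsFactors = FALSE)
  } else {
    cand <- enumerate_candidates(sentence)
    if (nrow(cand) == 0) return(list())
    pairs <- data.frame(id = paste0(sentence$id, ".p", seq_len(nrow(cand)) - 1L),
                        e1 = cand$e1, e2 = cand$e2, label = cand$label,
                        stringsAsFactors = FALSE)
  }
  ents <- sentence$entities
  names(ents) <- vapply(ents, `[[`, "", "id")
  lapply(seq_len(nrow(pairs)), function(i) {
    text <- blind(sentence, pairs$e1[i], pairs$e2[i])
    tokens <- tokenize_ddi(text)
    k <- which(tokens == "DRUG1")
    t_ <- which(tokens == "DRUG2")
    if (length(k) != 1 || length(t_) != 1) {
      stopf("sentence '%s', pair '%s': blinding did not yield exactly one DRUG1 and one DRUG2",
            sentence$id, pairs$id[i])
    }
    structure(list(
      instance_id = pairs$id[i],
      sentence_id = sentence$id,
      text = text,
      tokens = tokens,
      e1_index = k,
      e2_index = t_,
      label = pairs$label[i],
      e1_text = ents[[pairs$e1[i]]]$text,
      e2_text = ents[[pairs$e2[i]]]$text,
      e1_span = ents[[pairs$e1[i]]]$char_spans[1, ],
      e2_span = ents[[pairs$e2[i]]]$char_spans[1, ],
      sentence_text = sentence$text
    ), class = "ddi_instance")
  })
}

#' Extract candidate instances from a whole corpus
#'
#' Convenience pipeline over [candidate_instances()], optionally followed by
#' [filter_negatives()].
#'
#' @param docs list of [ddi_document()] objects.
#' @param filter apply negative-instance filtering.
#' @param rules filtering rules to enable, a subset of `c("R1","R2","R3")`.
#' @param use_annotated_pairs see [candidate_instances()].
#' @return A list with `instances` (retained), `removed` (the filter log as a
#'   data frame) and `class_counts` (named integer vector over
#'   [ddi_classes()], after filtering).
#' @export
corpus_instances <- function(docs, filter = TRUE, rules = c("R1", "R2", "R3"),
                             use_annotated_pairs = TRUE) {
  inst <- list()
  for (d in docs) {
    for (s in d$sentences) {
      inst <- c(inst, candidate_instances(s, use_annotated_pairs))
    }
  }
  if (filter) {
    fl <- filter_negatives(inst, rules = rules)
    inst <- fl$retained
    removed <- fl$removed
  } else {
    removed <- empty_filter_log()
  }
  labels <- vapply(inst, `[[`, "", "label")
  counts <- table(factor(labels, levels = ddi_classes()))
  list(instances = inst, removed = removed,
       class_counts = stats::setNames(as.integer(counts), ddi_classes()))
}

empty_filter_log <- function() {
  data.frame(instance_id = character(0), rule = character(0),
             e1_text = character(0), e2_text = character(0),
             stringsAsFactors = FALSE)
}

# Tokens that may sit between two coordinated mentions (rule R2).
coordinate_tokens <- c(",", ";", "and", "or", "/", "DRUG0")

filter_rule <- function(inst, rules) {
  e1 <- tolower(trimws(inst$e1_text))
  e2 <- tolower(trimws(inst$e2_text))
  between_tokens <- {
    lo <- min(inst$e1_index, inst$e2_index)
    hi <- max(inst$e1_index, inst$e2_index)
    if (hi - lo > 1) inst$tokens[(lo + 1):(hi - 1)] else character(0)
  }
  if ("R1" %in% rules) {
    if (identical(e1, e2)) return("R1")
    # parenthesized abbreviation immediately following the other mention:
    # the only blinded content between the two mentions is "(" and the
    # second mention is directly followed by ")".
    first <- if (inst$e1_span[1] <= inst$e2_span[1]) inst$e1_span else inst$e2_span
    second <- if (inst$e1_span[1] <= inst$e2_span[1]) inst$e2_span else inst$e1_span
    gap <- substr(inst$sentence_text, first[2] + 2, second[1])
    after <- substr(inst$sentence_text, second[2] + 2, second[2] + 2)
    if (identical(gsub("[[:space:]]", "", gap), "(") && identical(after, ")")) {
      return("R1")
    }
  }
  if ("R2" %in% rules) {
    if (all(between_tokens %in% coordinate_tokens)) return("R2")
  }
  if ("R3" %in% rules) {
    if ((grepl(e1, e2, fixed = TRUE) || grepl(e2, e1, fixed = TRUE)) &&
        !identical(e1, e2)) {
      return("R3")
    }
    linker <- between_tokens[!(between_tokens %in%
                                 c(",", ";", "(", ")", ".", "DRUG0"))]
    if (paste(linker, collapse = " ") %in% c("such as", "including", "e g")) {
      return("R3")
    }
  }
  NA_character_
}

#' Filter trivially non-interacting negative candidates
#'
#' Removes a Negative-labelled instance when one of three rules fires:
#' * **R1** — the two mentions have the same name (case-insensitive), or one
#'   is a parenthesized abbreviation immediately following the other;
#' * **R2** — the mentions are members of a coordinate structure: every token
#'   strictly between them is one of `","`, `";"`, `"and"`, `"or"`, `"/"` or
#'   a `DRUG0`-blinded mention;
#' * **R3** — one mention's text is a strict substring of the other's, or the
#'   two are linked by "such as" / "including" / "e.g." with no other
#'   intervening content word.
#'
#' Positively labelled instances are never removed, whatever their surface
#' form. Each removal is logged with its rule id.
#'
#' @param instances list of instances from [candidate_instances()].
#' @param rules subset of `c("R1","R2","R3")`; rules can be toggled
#'   individually.
#' @return A list with `retained` (instances kept) and `removed` (data frame
#'   log with columns `instance_id`, `rule`, `e1_text`, `e2_text`).
#' @export
filter_negatives <- function(instances, rules = c("R1", "R2", "R3")) {
  rules <- match.arg(rules, c("R1", "R2", "R3"), several.ok = TRUE)
  keep <- logical(length(instances))
  log <- empty_filter_log()
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    rule <- if (inst$label == "Negative") filter_rule(inst, rules) else NA_character_
    if (is.na(rule)) {
      keep[i] <- TRUE
    } else {
      log <- rbind(log, data.frame(instance_id = inst$instance_id, rule = rule,
                                   e1_text = inst$e1_text, e2_text = inst$e2_text,
                                   stringsAsFactors = FALSE))
    }
  }
  list(retained = instances[keep], removed = log)
}

#' Build a token vocabulary
#'
#' Integer ids: 0 is reserved for padding, 1 for unknown tokens, known tokens
#' start at 2. The blinding symbols `DRUG0`/`DRUG1`/`DRUG2` are always
#' present.
#'
#' @param token_lists list of token character vectors (or of instances, whose
#'   `$tokens` field is then used).
#' @param min_count minimum corpus frequency for a token to receive an id.
#' @return An object of class `ddi_vocab`.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  if (length(token_lists) > 0 && is.list(token_lists[[1]]) &&
      !is.null(token_lists[[1]]$tokens)) {
    token_lists <- lapply(token_lists, `[[`, "tokens")
  }
  tab <- table(unlist(token_lists))
  toks <- names(tab)[tab >= min_count]
  toks <- union(c("DRUG0", "DRUG1", "DRUG2"), sort(toks))
  ids <- stats::setNames(seq_along(toks) + 1L, toks)  # ids start at 2
  structure(list(ids = ids, tokens = toks, size = length(toks) + 2L),
            class = "ddi_vocab")
}

#' @export
print.ddi_vocab <- function(x, ...) {
  cat("<ddi_vocab>", length(x$tokens), "tokens (+ pad, unk)\n")
  invisible(x)
}

#' Map tokens to integer ids
#'
#' @param vocab a `ddi_vocab`.
#' @param tokens character vector.
#' @return Integer ids; unknown tokens map to 1.
#' @export
vocab_ids <- function(vocab, tokens) {
  ids <- unname(vocab$ids[tokens])
  ids[is.na(ids)] <- 1L
  ids
}

#' Map integer ids back to tokens
#'
#' @param vocab a `ddi_vocab`.
#' @param ids integer vector; 0 maps to `"<pad>"`, 1 to `"<unk>"`.
#' @return Character vector of tokens.
#' @export
vocab_tokens <- function(vocab, ids) {
  out <- rep("<unk>", length(ids))
  out[ids == 0L] <- "<pad>"
  known <- ids >= 2L
  out[known] <- vocab$tokens[ids[known] - 1L]
  out
}

#' Write / read a vocabulary as a two-column text file
#'
#' @param vocab a `ddi_vocab`.
#' @param path file path.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` returns a
#'   `ddi_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(data.frame(token = vocab$tokens,
                                id = unname(vocab$ids[vocab$tokens])),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"),
                          quote = "", comment.char = "")
  structure(list(ids = stats::setNames(df$id, df$token), tokens = df$token,
                 size = max(df$id) + 1L),
            class = "ddi_vocab")
}

#' Encode an instance to fixed length with position features
#'
#' Token ids are padded with 0 to `max_len` or truncated. Relative distances
#' of each token to `DRUG1` and `DRUG2` are clipped to
#' `[-(max_len-1), max_len-1]` and shifted by `+max_len` so they index a
#' single embedding table (values in `[1, 2*max_len-1]`, 0 at padding
#' positions; the entity's own position maps to exactly `max_len`). When
#' plain head-truncation would drop an entity token the window is re-centred
#' so both entities survive whenever their span fits in `max_len`; otherwise
#' the instance is flagged (`flagged = TRUE`) rather than silently corrupted.
#'
#' @param instance a `ddi_instance` from [candidate_instances()].
#' @param vocab a `ddi_vocab`.
#' @param max_len maximum sequence length (>= 1).
#' @return An object of class `ddi_encoded` with fields `token_ids`, `dist1`,
#'   `dist2` (all length `max_len`), `length` (effective length), `label`,
#'   `label_id` (1-based index into [ddi_classes()]) and `flagged`.
#' @export
encode_instance <- function(instance, vocab, max_len = 150L) {
  stopifnot(max_len >= 1)
  tokens <- instance$tokens
  n <- length(tokens)
  k <- instance$e1_index
  t_ <- instance$e2_index
  flagged <- FALSE
  start <- 1L
  if (n > max_len) {
    lo <- min(k, t_); hi <- max(k, t_)
    if (hi <= max_len) {
      start <- 1L                      # head truncation keeps both entities
    } else if (hi - lo + 1L <= max_len) {
      start_min <- hi - max_len + 1L
      start_max <- min(lo, n - max_len + 1L)
      centred <- as.integer(floor((lo + hi) / 2) - floor(max_len / 2))
      start <- min(max(centred, start_min), start_max)
    } else {
      flagged <- TRUE                  # entities farther apart than max_len
      start <- 1L
    }
  }
  idx <- start:min(n, start + max_len - 1L)
  eff <- length(idx)
  k_rel <- k - start + 1L
  t_rel <- t_ - start + 1L
  ids <- integer(max_len)
  ids[seq_len(eff)] <- vocab_ids(vocab, tokens[idx])
  clip_shift <- function(d) pmax(pmin(d, max_len - 1L), -(max_len - 1L)) + max_len
  d1 <- integer(max_len)
  d2 <- integer(max_len)
  d1[seq_len(eff)] <- clip_shift(seq_len(eff) - k_rel)
  d2[seq_len(eff)] <- clip_shift(seq_len(eff) - t_rel)
  structure(list(instance_id = instance$instance_id,
                 token_ids = ids, dist1 = d1, dist2 = d2,
                 length = eff, label = instance$label,
                 label_id = match(instance$label, ddi_classes()),
                 flagged = flagged),
            class = "ddi_encoded")
}

#' @rdname encode_instance
#' @param instances list of instances.
#' @export
encode_instances <- function(instances, vocab, max_len = 150L) {
  lapply(instances, encode_instance, vocab = vocab, max_len = max_len)
}

#' Recover the unpadded token sequence of an encoded instance
#'
#' @param enc a `ddi_encoded`.
#' @param vocab the vocabulary used for encoding.
#' @return Character vector of tokens (unknown tokens come back as
#'   `"<unk>"`).
#' @export
decode_instance <- function(enc, vocab) {
  vocab_tokens(vocab, enc$token_ids[seq_len(enc$length)])
}
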