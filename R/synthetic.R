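# Synthetic labelled DDI-style corpus generator. Sentences instantiate
# class-specific templates whose trigger phrases carry the label signal
# (Advice: "should not be coadministered with", Effect: "may potentiate the
# effect of", Mechanism: "increases the plasma concentration of", Int: "may
# interact with"; Negative sentences co-mention two drugs without interaction
# wording). Entity character offsets are exact, so every generated corpus
# round-trips through the XML reader/writer and exercises the full pipeline
# without the licensed benchmark download.

syn_templates <- function(hard_mode = FALSE) {
  tpl <- list(
    Advice = c(
      "{E1} should not be coadministered with {E2}.",
      "caution is advised when {E1} is given together with {E2}.",
      "concomitant use of {E1} with {E2} is not recommended.",
      "the dose of {E2} should be reduced during treatment with {E1}."
    ),
    Effect = c(
      "{E1} may potentiate the effect of {E2}.",
      "{E1} may enhance the hypotensive action of {E2}.",
      "coadministration of {E1} increased the sedative effect of {E2}.",
      "{E1} augments the anticoagulant response to {E2}."
    ),
    Mechanism = c(
      "{E1} increases the plasma concentration of {E2}.",
      "{E1} reduces the renal clearance of {E2}.",
      "{E1} inhibits the hepatic metabolism of {E2}.",
      "{E1} decreased the absorption of {E2} by 00 percent."
    ),
    Int = c(
      "{E1} may interact with {E2}.",
      "a potential interaction of {E1} with {E2} has been reported.",
      "{E1} is known to interact with {E2}."
    ),
    Negative = c(
      "{E1} had no significant effect on the pharmacokinetics of {E2}.",
      "{E1} did not alter the disposition of {E2} in healthy volunteers.",
      "the interaction potential of {E1} with respect to {E2} has not been determined.",
      "{E1} was measured before administration of {E2} in this study."
    )
  )
  if (hard_mode) {
    # overlap the Int and Effect trigger vocabulary to mimic the Int->Effect
    # confusion seen on real data
    tpl$Int <- c(tpl$Int, "{E1} may interact with the effect of {E2}.")
    tpl$Effect <- c(tpl$Effect, "{E1} may potentiate and interact with {E2}.")
  }
  tpl
}

#' Synthetic-corpus configuration
#'
#' The default class proportions follow the filtered training distribution of
#' the benchmark corpus (about 3.6% Advice, 7.3% Effect, 5.7% Mechanism,
#' 0.8% Int, 82.6% Negative).
#'
#' @param n_sentences number of sentences to generate (>= 1).
#' @param class_proportions named or positional numeric vector over the five
#'   classes in [ddi_classes()] order; must sum to 1.
#' @param lexicon_size number of invented drug names to sample from.
#' @param distractor_rate probability that a sentence carries an extra
#'   (non-candidate) drug mention.
#' @param hard_mode add templates whose trigger phrases overlap between the
#'   Int and Effect classes.
#' @param sentences_per_doc sentences grouped per output document.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return An object of class `ddi_generator_config`.
#' @export
generator_config <- function(n_sentences = 1000L,
                             class_proportions = c(Advice = 0.036,
                                                   Effect = 0.073,
                                                   Mechanism = 0.057,
                                                   Int = 0.008,
                                                   Negative = 0.826),
                             lexicon_size = 150L, distractor_rate = 0.3,
                             hard_mode = FALSE, sentences_per_doc = 25L,
                             seed = 1L) {
  stopifnot(n_sentences >= 1, lexicon_size >= 4,
            distractor_rate >= 0, distractor_rate <= 1,
            sentences_per_doc >= 1)
  class_proportions <- as.numeric(class_proportions)
  if (length(class_proportions) != 5 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stopf("class_proportions must be 5 non-negative values summing to 1")
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 class_proportions = stats::setNames(class_proportions,
                                                     ddi_classes()),
                 lexicon_size = as.integer(lexicon_size),
                 distractor_rate = distractor_rate,
                 hard_mode = isTRUE(hard_mode),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 seed = as.integer(seed)),
            class = "ddi_generator_config")
}

#' Invented drug-name lexicon
#'
#' Deterministic pseudo-pharmaceutical names built from syllables. No name is
#' a substring of another, so the names never trip the substring filtering
#' rule by accident.
#'
#' @param n number of names.
#' @return Character vector of `n` unique names.
#' @export
drug_lexicon <- function(n = 150L) {
  pre <- c("al", "bex", "cor", "dal", "ex", "flu", "gan", "hep", "ib", "kel",
           "lor", "mav", "nor", "os", "pra", "quin", "rov", "sul", "tri",
           "vel", "zon")
  mid <- c("pi", "ra", "ve", "do", "mi", "ta", "lu", "fe", "xi", "ne")
  suf <- c("zole", "mab", "statin", "cillin", "micin", "pril", "sartan",
           "olol", "oxetine", "dipine", "navir", "axel")
  grid <- expand.grid(pre = pre, mid = mid, suf = suf,
                      stringsAsFactors = FALSE)
  names_all <- paste0(grid$pre, grid$mid, grid$suf)
  keep <- character(0)
  for (nm in names_all) {
    if (length(keep) >= n) break
    if (!any(vapply(keep, function(k) grepl(k, nm, fixed = TRUE) ||
                      grepl(nm, k, fixed = TRUE), logical(1)))) {
      keep <- c(keep, nm)
    }
  }
  if (length(keep) < n) stopf("lexicon can supply at most %d names", length(keep))
  keep
}

# Instantiate a template: returns text plus 0-based inclusive spans for each
# placeholder, in placeholder order E1, E2[, E0].
fill_template <- function(tpl, values) {
  spans <- list()
  text <- ""
  rest <- tpl
  repeat {
    m <- regexpr("\\{E[012]\\}", rest)
    if (m == -1) {
      text <- paste0(text, rest)
      break
    }
    text <- paste0(text, substr(rest, 1, m - 1))
    slot <- substr(rest, m + 1, m + 2)  # "E1", "E2", "E0"
    val <- values[[slot]]
    start0 <- nchar(text)
    text <- paste0(text, val)
    spans[[slot]] <- c(start = start0, end = start0 + nchar(val) - 1L)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  list(text = text, spans = spans)
}

#' Generate a synthetic DDI corpus
#'
#' @param cfg a [generator_config()].
#' @return List of [ddi_document()] objects; each sentence has at least two
#'   entity mentions with exact character offsets, one annotated candidate
#'   pair carrying the template's label, and `ddi="false"` pairs for any
#'   distractor combinations.
#' @export
generate_ddi_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "ddi_generator_config"))
  tpls <- syn_templates(cfg$hard_mode)
  lex <- drug_lexicon(cfg$lexicon_size)
  with_seed(cfg$seed, {
    labels <- sample(ddi_classes(), cfg$n_sentences, replace = TRUE,
                     prob = cfg$class_proportions)
    sentences <- vector("list", cfg$n_sentences)
    for (i in seq_len(cfg$n_sentences)) {
      lab <- labels[i]
      tpl <- sample(tpls[[lab]], 1)
      with_distractor <- stats::runif(1) < cfg$distractor_rate
      if (with_distractor) {
        tpl <- sub("\\.$", ", particularly in patients also receiving {E0}.",
                   tpl)
      }
      drugs <- sample(lex, if (with_distractor) 3L else 2L)
      ft <- fill_template(tpl, list(E1 = drugs[1], E2 = drugs[2],
                                    E0 = if (with_distractor) drugs[3]))
      sid <- sprintf("SYN.d%d.s%d", (i - 1L) %/% cfg$sentences_per_doc,
                     (i - 1L) %% cfg$sentences_per_doc)
      ents <- list()
      for (slot in names(ft$spans)) {
        ents[[slot]] <- ddi_entity(id = paste0(sid, ".e", length(ents)),
                                   char_spans = ft$spans[[slot]],
                                   text = values_from_span(ft$text,
                                                           ft$spans[[slot]]),
                                   entity_type = "drug")
      }
      pairs <- list(ddi_pair(paste0(sid, ".p0"), ents$E1$id, ents$E2$id, lab))
      if (!is.null(ents$E0)) {
        pairs <- c(pairs,
                   list(ddi_pair(paste0(sid, ".p1"), ents$E1$id, ents$E0$id,
                                 "Negative"),
                        ddi_pair(paste0(sid, ".p2"), ents$E2$id, ents$E0$id,
                                 "Negative")))
      }
      sentences[[i]] <- ddi_sentence(sid, ft$text, unname(ents), pairs)
    }
    split_idx <- (seq_len(cfg$n_sentences) - 1L) %/% cfg$sentences_per_doc
    docs <- lapply(sort(unique(split_idx)), function(dix) {
      ddi_document(sprintf("SYN.d%d", dix), sentences[split_idx == dix])
    })
    docs
  })
}

values_from_span <- function(text, span) {
  substr(text, span[1] + 1L, span[2] + 1L)
}

#' Write the gold pair labels of a corpus as TSV
#'
#' @param docs list of [ddi_document()] objects.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gold_tsv <- function(docs, path) {
  rows <- list()
  for (d in docs) for (s in d$sentences) for (p in s$pairs) {
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = p$id, sentence_id = s$id, e1 = p$e1_id, e2 = p$e2_id,
      label = p$label, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), sentence_id = character(0),
               e1 = character(0), e2 = character(0), label = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hand-constructed fixtures for the negative-filtering rules
#'
#' Builds sentences guaranteed to trigger each filtering rule exactly once
#' (same-name pair, parenthesized abbreviation, coordinate list, "such as"
#' specialization, substring specialization) plus matched controls that must
#' be retained, including a positively labelled instance with a coordinate
#' surface form (positives are never filtered).
#'
#' @return Named list of `ddi_instance` objects; each carries an
#'   `expected_rule` field (`"R1"`, `"R2"`, `"R3"` or `NA` for controls that
#'   must survive filtering).
#' @export
generate_filter_fixtures <- function() {
  mk <- function(name, text, mentions, label, expected_rule,
                 pair = c(1L, 2L)) {
    ents <- lapply(seq_along(mentions), function(j) {
      m <- mentions[[j]]
      ddi_entity(paste0("FIX.", name, ".e", j - 1L), c(m$start, m$end),
                 values_from_span(text, c(m$start, m$end)))
    })
    ids <- vapply(ents, `[[`, "", "id")
    s <- ddi_sentence(paste0("FIX.", name), text, ents,
                      list(ddi_pair(paste0("FIX.", name, ".p0"),
                                    ids[pair[1]], ids[pair[2]], label)))
    inst <- candidate_instances(s)[[1]]
    inst$expected_rule <- expected_rule
    inst
  }
  span_of <- function(text, what, occurrence = 1L) {
    m <- gregexpr(what, text, fixed = TRUE)[[1]]
    st <- m[occurrence] - 1L
    list(start = st, end = st + nchar(what) - 1L)
  }
  out <- list()
  t1 <- "grepafloxacin modifies the metabolism of grepafloxacin in vitro."
  out$r1_same <- mk("r1same", t1,
                    list(span_of(t1, "grepafloxacin", 1),
                         span_of(t1, "grepafloxacin", 2)),
                    "Negative", "R1")
  t2 <- "acetylsalicylic acid (ASA) was studied together with warfarin."
  out$r1_abbrev <- mk("r1abbr", t2,
                      list(span_of(t2, "acetylsalicylic acid"),
                           span_of(t2, "ASA"), span_of(t2, "warfarin")),
                      "Negative", "R1")
  t3 <- "alprazolam, diazepam and lorazepam were studied in volunteers."
  out$r2_coord <- mk("r2coord", t3,
                     list(span_of(t3, "alprazolam"), span_of(t3, "diazepam"),
                          span_of(t3, "lorazepam")),
                     "Negative", "R2")
  t4 <- "beta blockers such as propranolol were reviewed separately."
  out$r3_suchas <- mk("r3such", t4,
                      list(span_of(t4, "beta blockers"),
                           span_of(t4, "propranolol")),
                      "Negative", "R3")
  t5 <- "metformin hydrochloride tablets were compared against plain metformin."
  out$r3_substr <- mk("r3sub", t5,
                      list(span_of(t5, "metformin hydrochloride"),
                           span_of(t5, "metformin", 2)),
                      "Negative", "R3")
  t6 <- "alprazolam increased the sedation produced by diazepam."
  out$control_negative <- mk("ctrlneg", t6,
                             list(span_of(t6, "alprazolam"),
                                  span_of(t6, "diazepam")),
                             "Negative", NA_character_)
  t7 <- "alprazolam, diazepam and lorazepam interact strongly."
  out$control_positive <- mk("ctrlpos", t7,
                             list(span_of(t7, "alprazolam"),
                                  span_of(t7, "diazepam"),
                                  span_of(t7, "lorazepam")),
                             "Effect", NA_character_)
  out
}
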