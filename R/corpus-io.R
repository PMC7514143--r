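# Reading, writing and validating the DDIExtraction-2013 XML dialect:
#   <document id> / <sentence id text> / <entity id charOffset text type>
#   / <pair id e1 e2 ddi [type]>
# Character offsets are 0-based with inclusive end ("0-5" covers six
# characters); discontinuous mentions use ";"-separated spans ("a-b;c-d").

#' Construct a drug entity mention
#'
#' @param id entity identifier, unique within its sentence.
#' @param char_spans integer matrix with two columns (start, end) or a vector
#'   `c(start, end)`; offsets are 0-based with inclusive end. Discontinuous
#'   mentions have one row per span; spans must be ordered and
#'   non-overlapping.
#' @param text the surface form of the mention.
#' @param entity_type one of `"drug"`, `"brand"`, `"group"`, `"drug_n"` or a
#'   synthetic type.
#' @return An object of class `ddi_entity`.
#' @export
ddi_entity <- function(id, char_spans, text, entity_type = "drug") {
  if (is.vector(char_spans) && !is.list(char_spans)) {
    char_spans <- matrix(as.integer(char_spans), ncol = 2, byrow = TRUE)
  }
  char_spans <- matrix(as.integer(char_spans), ncol = 2,
                       dimnames = list(NULL, c("start", "end")))
  if (nrow(char_spans) < 1) stopf("entity '%s' has no character span", id)
  if (any(char_spans[, 2] < char_spans[, 1])) {
    stopf("entity '%s' has a span with end < start", id)
  }
  if (nrow(char_spans) > 1) {
    o <- order(char_spans[, 1])
    char_spans <- char_spans[o, , drop = FALSE]
    if (any(char_spans[-1, 1] <= char_spans[-nrow(char_spans), 2])) {
      stopf("entity '%s' has overlapping spans", id)
    }
  }
  structure(list(id = id, char_spans = char_spans, text = text,
                 entity_type = entity_type),
            class = "ddi_entity")
}

#' Construct a drug-pair annotation
#'
#' @param id pair identifier.
#' @param e1_id,e2_id ids of the two entity mentions (must differ).
#' @param label one of the five classes from [ddi_classes()]; `"Negative"`
#'   means the sentence does not assert an interaction for this pair.
#' @return An object of class `ddi_pair`.
#' @export
ddi_pair <- function(id, e1_id, e2_id, label = "Negative") {
  if (identical(e1_id, e2_id)) stopf("pair '%s' references the same entity twice", id)
  label <- canonical_label(label)
  structure(list(id = id, e1_id = e1_id, e2_id = e2_id, label = label),
            class = "ddi_pair")
}

canonical_label <- function(label) {
  m <- match(tolower(label), tolower(ddi_classes()))
  if (anyNA(m)) stopf("unknown DDI label '%s'", paste(label[is.na(m)], collapse = ", "))
  ddi_classes()[m]
}

#' Construct a sentence record
#'
#' @param id sentence identifier.
#' @param text sentence text.
#' @param entities list of [ddi_entity()] mentions.
#' @param pairs list of [ddi_pair()] annotations; every pair must reference
#'   entities of this sentence.
#' @return An object of class `ddi_sentence`.
#' @export
ddi_sentence <- function(id, text, entities = list(), pairs = list()) {
  s <- structure(list(id = id, text = text, entities = entities, pairs = pairs),
                 class = "ddi_sentence")
  validate_sentence(s)
  s
}

validate_sentence <- function(s) {
  ids <- vapply(s$entities, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("sentence '%s' has duplicate entity ids", s$id)
  n <- nchar(s$text)
  for (e in s$entities) {
    if (any(e$char_spans < 0) || any(e$char_spans[, 2] >= n)) {
      stopf("sentence '%s': entity '%s' span out of range of sentence text",
            s$id, e$id)
    }
  }
  m <- length(s$entities)
  if (length(s$pairs) > choose(m, 2)) {
    stopf("sentence '%s' annotates more pairs than C(%d,2)", s$id, m)
  }
  for (p in s$pairs) {
    if (!all(c(p$e1_id, p$e2_id) %in% ids)) {
      stopf("sentence '%s': pair '%s' references unknown entity id", s$id, p$id)
    }
  }
  invisible(s)
}

#' Construct a document
#'
#' @param id document identifier.
#' @param sentences list of [ddi_sentence()] records with unique ids.
#' @return An object of class `ddi_document`.
#' @export
ddi_document <- function(id, sentences = list()) {
  sids <- vapply(sentences, `[[`, "", "id")
  if (anyDuplicated(sids)) stopf("document '%s' has duplicate sentence ids", id)
  structure(list(id = id, sentences = sentences), class = "ddi_document")
}

parse_char_offset <- function(x) {
  spans <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- strsplit(spans, "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

format_char_offset <- function(spans) {
  paste(apply(spans, 1, function(r) paste0(r[1], "-", r[2])), collapse = ";")
}

#' Read a corpus in the DDIExtraction-2013 XML dialect
#'
#' `path` may be a single XML file or a directory, in which case every
#' `*.xml` file in it is read. A file may contain either a single
#' `<document>` root or a root element wrapping several `<document>`
#' elements. Pairs with `ddi="true"` carry their `type` attribute; pairs with
#' `ddi="false"` are labelled `"Negative"`.
#'
#' @param path file or directory path.
#' @return A list of [ddi_document()] objects.
#' @export
read_ddi_corpus <- function(path) {
  if (!file.exists(path)) stopf("corpus path '%s' does not exist", path)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else {
    path
  }
  docs <- list()
  for (f in files) {
    x <- tryCatch(xml2::read_xml(f), error = function(e) {
      stopf("malformed XML in '%s': %s", f, conditionMessage(e))
    })
    nodes <- if (xml2::xml_name(x) == "document") list(x) else
      xml2::xml_find_all(x, ".//document")
    for (d in nodes) docs[[length(docs) + 1L]] <- parse_document_node(d, f)
  }
  docs
}

parse_document_node <- function(node, file) {
  sents <- lapply(xml2::xml_find_all(node, "./sentence"), function(sn) {
    ents <- lapply(xml2::xml_find_all(sn, "./entity"), function(en) {
      ddi_entity(id = xml2::xml_attr(en, "id"),
                 char_spans = parse_char_offset(xml2::xml_attr(en, "charOffset")),
                 text = xml2::xml_attr(en, "text"),
                 entity_type = xml2::xml_attr(en, "type"))
    })
    prs <- lapply(xml2::xml_find_all(sn, "./pair"), function(pn) {
      ddi <- tolower(xml2::xml_attr(pn, "ddi"))
      label <- if (identical(ddi, "true")) xml2::xml_attr(pn, "type") else "Negative"
      ddi_pair(id = xml2::xml_attr(pn, "id"),
               e1_id = xml2::xml_attr(pn, "e1"),
               e2_id = xml2::xml_attr(pn, "e2"),
               label = label)
    })
    tryCatch(
      ddi_sentence(id = xml2::xml_attr(sn, "id"),
                   text = xml2::xml_attr(sn, "text"),
                   entities = ents, pairs = prs),
      error = function(e) stopf("invalid sentence in '%s': %s",
                                file, conditionMessage(e)))
  })
  ddi_document(id = xml2::xml_attr(node, "id"), sentences = sents)
}

#' Write documents in the DDIExtraction-2013 XML dialect
#'
#' Each document is written to `<path>/<document id>.xml`; the output
#' round-trips exactly through [read_ddi_corpus()].
#'
#' @param docs list of [ddi_document()] objects.
#' @param path output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_ddi_corpus <- function(docs, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) stopf("cannot create output directory '%s'", path)
  }
  written <- character(0)
  for (doc in docs) {
    x <- xml2::xml_new_root("document", id = doc$id)
    for (s in doc$sentences) {
      sn <- xml2::xml_add_child(x, "sentence", id = s$id, text = s$text)
      for (e in s$entities) {
        xml2::xml_add_child(sn, "entity", id = e$id,
                            charOffset = format_char_offset(e$char_spans),
                            type = e$entity_type, text = e$text)
      }
      for (p in s$pairs) {
        if (p$label == "Negative") {
          xml2::xml_add_child(sn, "pair", id = p$id, e1 = p$e1_id, e2 = p$e2_id,
                              ddi = "false")
        } else {
          xml2::xml_add_child(sn, "pair", id = p$id, e1 = p$e1_id, e2 = p$e2_id,
                              ddi = "true", type = tolower(p$label))
        }
      }
    }
    f <- file.path(path, paste0(doc$id, ".xml"))
    xml2::write_xml(x, f)
    written <- c(written, f)
  }
  invisible(written)
}

#' Enumerate candidate drug pairs of a sentence
#'
#' A sentence with m entity mentions yields C(m,2) unordered candidate pairs,
#' listed with e1 preceding e2 in document order. When the sentence carries
#' pair annotations, the label of a matching annotation (in either order) is
#' used; unannotated pairs default to `"Negative"` (the synthetic-corpus
#' convention).
#'
#' @param sentence a [ddi_sentence()].
#' @return A data frame with columns `e1`, `e2` (entity ids) and `label`.
#' @export
enumerate_candidates <- function(sentence) {
  validate_sentence(sentence)
  ents <- sentence$entities
  if (length(ents) < 2) {
    return(data.frame(e1 = character(0), e2 = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  starts <- vapply(ents, function(e) e$char_spans[1, 1], integer(1))
  ents <- ents[order(starts)]
  ids <- vapply(ents, `[[`, "", "id")
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  ann <- list()
  for (p in sentence$pairs) ann[[key(p$e1_id, p$e2_id)]] <- p$label
  combs <- utils::combn(seq_along(ids), 2)
  e1 <- ids[combs[1, ]]
  e2 <- ids[combs[2, ]]
  label <- mapply(function(a, b) ann[[key(a, b)]] %||% "Negative", e1, e2)
  data.frame(e1 = e1, e2 = e2, label = unname(label), stringsAsFactors = FALSE)
}

#' Export candidate instances as JSON lines
#'
#' One JSON object per line with the instance id, sentence id, blinded text
#' and label, for manual inspection of the preprocessing output.
#'
#' @param instances list of candidate instances (see [candidate_instances()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_instances_jsonl <- function(instances, path) {
  lines <- vapply(instances, function(x) {
    jsonlite::toJSON(list(instance_id = x$instance_id,
                          sentence_id = x$sentence_id,
                          text = x$text, label = x$label),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
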