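test_that("drug blinding reproduces the three worked candidate variants", {
  s <- table1_sentence()
  expect_equal(blind(s, "e0", "e1"),
               "DRUG1 modifies DRUG2 metabolism with increased serum levels of DRUG0.")
  expect_equal(blind(s, "e0", "e2"),
               "DRUG1 modifies DRUG0 metabolism with increased serum levels of DRUG2.")
  expect_equal(blind(s, "e1", "e2"),
               "DRUG0 modifies DRUG1 metabolism with increased serum levels of DRUG2.")
})

test_that("the three blinded variants of one sentence are token-aligned", {
  s <- table1_sentence()
  variants <- list(blind(s, "e0", "e1"), blind(s, "e0", "e2"),
                   blind(s, "e1", "e2"))
  toks <- lapply(variants, tokenize_ddi)
  expect_length(unique(vapply(toks, length, integer(1))), 1)
  # non-entity tokens agree position by position
  drug <- function(x) grepl("^DRUG[012]$", x)
  for (i in 2:3) {
    expect_equal(toks[[1]][!drug(toks[[1]])], toks[[i]][!drug(toks[[i]])])
  }
})

test_that("blinding a two-mention sentence yields DRUG1 and DRUG2 and no DRUG0", {
  s <- ddi_sentence("s2", "aspirin interacts with warfarin.",
                    list(ddi_entity("e0", c(0, 6), "aspirin"),
                         ddi_entity("e1", c(23, 30), "warfarin")))
  b <- tokenize_ddi(blind(s, "e0", "e1"))
  expect_equal(sum(b == "DRUG1"), 1)
  expect_equal(sum(b == "DRUG2"), 1)
  expect_false("DRUG0" %in% b)
})

test_that("blinding rejects out-of-range spans", {
  expect_error(
    ddi_sentence("bad", "short.", list(ddi_entity("e0", c(0, 40), "short"))),
    "out of range")
})

test_that("tokenization splits punctuation, lowercases, and normalizes digits", {
  expect_equal(tokenize_ddi("DRUG1 modifies DRUG2 metabolism."),
               c("DRUG1", "modifies", "DRUG2", "metabolism", "."))
  expect_equal(tokenize_ddi(""), character(0))
  expect_equal(tokenize_ddi("decreased the zidovudine tmax by 44%"),
               c("decreased", "the", "zidovudine", "tmax", "by", "00", "%"))
  # blinding symbols are exempt from lowercasing and digit normalization
  expect_equal(tokenize_ddi("DRUG1, DRUG0!"), c("DRUG1", ",", "DRUG0", "!"))
})

test_that("each filtering rule fires on its fixture and spares the controls", {
  fx <- generate_filter_fixtures()
  res <- filter_negatives(fx)
  removed <- res$removed
  for (nm in names(fx)) {
    expected <- fx[[nm]]$expected_rule
    hit <- removed$rule[removed$instance_id == fx[[nm]]$instance_id]
    if (is.na(expected)) {
      expect_length(hit, 0)
    } else {
      expect_equal(hit, expected)
    }
  }
  # removal bookkeeping: retained + removed partitions the input
  expect_equal(length(res$retained) + nrow(removed), length(fx))
})

test_that("rules are individually toggleable", {
  fx <- generate_filter_fixtures()
  r2_only <- filter_negatives(fx, rules = "R2")
  expect_setequal(r2_only$removed$rule, "R2")
  expect_true(fx$r1_same$instance_id %in%
                vapply(r2_only$retained, `[[`, "", "instance_id"))
})

test_that("positive instances are never filtered, whatever their surface form", {
  fx <- generate_filter_fixtures()
  positives <- lapply(fx, function(x) { x$label <- "Effect"; x })
  res <- filter_negatives(positives)
  expect_length(res$retained, length(fx))
  expect_equal(nrow(res$removed), 0)
})

test_that("filtering never changes the positive-instance count of a corpus", {
  docs <- generate_ddi_corpus(generator_config(n_sentences = 120, seed = 4))
  unfiltered <- corpus_instances(docs, filter = FALSE)
  filtered <- corpus_instances(docs, filter = TRUE)
  n_pos <- function(x) sum(vapply(x$instances, `[[`, "", "label") != "Negative")
  expect_equal(n_pos(filtered), n_pos(unfiltered))
  expect_equal(length(filtered$instances) + nrow(filtered$removed),
               length(unfiltered$instances))
})

test_that("vocabulary ids are bijective with pad/unk reserved and round-trip through disk", {
  v <- build_vocab(list(c("alpha", "beta"), c("beta", "gamma")))
  expect_true(all(c("DRUG0", "DRUG1", "DRUG2") %in% v$tokens))
  expect_true(all(v$ids >= 2))
  expect_equal(anyDuplicated(v$ids), 0)
  expect_equal(vocab_ids(v, c("alpha", "never-seen")),
               c(unname(v$ids["alpha"]), 1L))
  expect_equal(vocab_tokens(v, c(0L, 1L, v$ids[["beta"]])),
               c("<pad>", "<unk>", "beta"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_vocab(v, f)
  v2 <- read_vocab(f)
  expect_equal(v2$ids, v$ids)
})

test_that("encoding pads with zeros and centres distances on the entities", {
  s <- table1_sentence()
  inst <- candidate_instances(s)[[1]]
  v <- build_vocab(list(inst))
  enc <- encode_instance(inst, v, max_len = 150L)
  n <- length(inst$tokens)
  expect_equal(enc$length, n)
  expect_true(all(enc$token_ids[(n + 1):150] == 0))
  expect_true(all(enc$dist1[(n + 1):150] == 0))
  # distance of each entity token to itself is 0, i.e. the shifted value max_len
  expect_equal(enc$dist1[inst$e1_index], 150L)
  expect_equal(enc$dist2[inst$e2_index], 150L)
  expect_equal(enc$label_id, match("Mechanism", ddi_classes()))
})

test_that("head truncation keeps both entities when they fit in the window", {
  toks <- c(rep("filler", 4), "DRUG1", rep("filler", 14), "DRUG2",
            rep("filler", 180))
  inst <- structure(list(instance_id = "t", sentence_id = "s",
                         text = paste(toks, collapse = " "), tokens = toks,
                         e1_index = 5L, e2_index = 20L, label = "Effect"),
                    class = "ddi_instance")
  v <- build_vocab(list(inst))
  enc <- encode_instance(inst, v, max_len = 150L)
  expect_false(enc$flagged)
  expect_equal(enc$length, 150L)
  dec <- decode_instance(enc, v)
  expect_equal(dec, toks[1:150])           # first 150 tokens retained
  expect_equal(which(dec == "DRUG1"), 5L)
  expect_equal(which(dec == "DRUG2"), 20L)
})

test_that("truncation re-centres when entities fall outside the head window, flags when impossible", {
  toks <- c(rep("x", 160), "DRUG1", rep("y", 10), "DRUG2", rep("z", 40))
  inst <- structure(list(instance_id = "t", tokens = toks,
                         e1_index = 161L, e2_index = 172L, label = "Effect"),
                    class = "ddi_instance")
  v <- build_vocab(list(inst))
  enc <- encode_instance(inst, v, max_len = 30L)
  expect_false(enc$flagged)
  dec <- decode_instance(enc, v)
  expect_true(all(c("DRUG1", "DRUG2") %in% dec))
  expect_equal(enc$dist1[which(dec == "DRUG1")], 30L)

  far <- structure(list(instance_id = "f", tokens = c("DRUG1", rep("x", 100), "DRUG2"),
                        e1_index = 1L, e2_index = 102L, label = "Effect"),
                   class = "ddi_instance")
  enc_far <- encode_instance(far, build_vocab(list(far)), max_len = 30L)
  expect_true(enc_far$flagged)
})

test_that("encode then decode recovers the unpadded token sequence", {
  docs <- generate_ddi_corpus(generator_config(n_sentences = 25, seed = 6))
  inst <- corpus_instances(docs, filter = FALSE)$instances
  v <- build_vocab(inst)
  for (x in inst[seq(1, length(inst), by = 7)]) {
    enc <- encode_instance(x, v, max_len = 60L)
    expect_equal(decode_instance(enc, v), x$tokens)
  }
})
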