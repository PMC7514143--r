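test_that("a sentence with three mentions parses into one record with its pairs", {
  dir <- withr::local_tempdir()
  write_ddi_corpus(list(ddi_document("Acetazolamide-ddi",
                                     list(table1_sentence()))), dir)
  docs <- read_ddi_corpus(dir)
  expect_length(docs, 1)
  expect_length(docs[[1]]$sentences, 1)
  s <- docs[[1]]$sentences[[1]]
  expect_length(s$entities, 3)
  expect_length(s$pairs, 3)
  expect_equal(vapply(s$pairs, `[[`, "", "label"),
               c("Mechanism", "Mechanism", "Negative"))
  expect_equal(s$entities[[3]]$char_spans[1, ], c(start = 68L, end = 76L))
})

test_that("an empty document element yields a document with zero sentences", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<document id="empty"/>', f)
  docs <- read_ddi_corpus(f)
  expect_length(docs, 1)
  expect_length(docs[[1]]$sentences, 0)
})

test_that("write then read is the identity on the object graph", {
  # includes a discontinuous mention whose offset encoding must survive
  s <- ddi_sentence(
    "d0.s0", "vitamin a and d supplements were taken with warfarin daily.",
    entities = list(
      ddi_entity("d0.s0.e0", matrix(c(0L, 8L, 14L, 26L), 2, 2, byrow = TRUE),
                 "vitamin a d supplements"),
      ddi_entity("d0.s0.e1", c(44, 51), "warfarin")),
    pairs = list(ddi_pair("d0.s0.p0", "d0.s0.e0", "d0.s0.e1", "Negative")))
  docs <- list(ddi_document("d0", list(s)),
               ddi_document("d1", list()))
  dir <- withr::local_tempdir()
  write_ddi_corpus(docs, dir)
  expect_identical(read_ddi_corpus(dir), docs)
})

test_that("round-trip preserves randomly generated corpora exactly", {
  docs <- generate_ddi_corpus(generator_config(n_sentences = 30, seed = 9))
  dir <- withr::local_tempdir()
  write_ddi_corpus(docs, dir)
  expect_identical(read_ddi_corpus(dir), docs)
})

test_that("writing zero documents produces no files and no error", {
  dir <- withr::local_tempdir()
  expect_no_error(write_ddi_corpus(list(), dir))
  expect_length(list.files(dir, pattern = "\\.xml$"), 0)
})

test_that("malformed XML and dangling entity references raise errors naming the file", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<document id='x'><sentence id='s'", bad)
  expect_error(read_ddi_corpus(bad), "malformed XML.*\\.xml")
  dangling <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0('<document id="x"><sentence id="s" text="aspirin and heparin.">',
                    '<entity id="e0" charOffset="0-6" type="drug" text="aspirin"/>',
                    '<entity id="e1" charOffset="12-18" type="drug" text="heparin"/>',
                    '<pair id="p0" e1="e0" e2="missing" ddi="false"/>',
                    "</sentence></document>"), dangling)
  expect_error(read_ddi_corpus(dangling), "unknown entity id")
})

test_that("candidate enumeration yields C(m,2) pairs with annotated labels", {
  expect_equal(nrow(enumerate_candidates(table1_sentence())), 3)

  # 5 mentions, 3 positive annotations -> 10 candidates, 3 positive, 7 negative
  txt <- "aaa bbb ccc ddd eee interact."
  ents <- lapply(0:4, function(i)
    ddi_entity(paste0("e", i), c(i * 4L, i * 4L + 2L), substr(txt, i * 4 + 1, i * 4 + 3)))
  s <- ddi_sentence("s5", txt, ents,
                    list(ddi_pair("p0", "e0", "e3", "Mechanism"),
                         ddi_pair("p1", "e1", "e3", "Effect"),
                         ddi_pair("p2", "e2", "e3", "Effect")))
  cand <- enumerate_candidates(s)
  expect_equal(nrow(cand), 10)
  expect_equal(sum(cand$label != "Negative"), 3)
  expect_equal(sum(cand$label == "Negative"), 7)

  # single mention -> no candidates
  s1 <- ddi_sentence("s1", "aspirin alone.",
                     list(ddi_entity("e0", c(0, 6), "aspirin")))
  expect_equal(nrow(enumerate_candidates(s1)), 0)
})

test_that("enumeration count matches m(m-1)/2 for random mention counts", {
  for (m in 2:6) {
    txt <- paste(rep("drugx", m), collapse = " ")
    ents <- lapply(seq_len(m) - 1L, function(i)
      ddi_entity(paste0("e", i), c(i * 6L, i * 6L + 4L), "drugx"))
    s <- ddi_sentence(paste0("s", m), txt, ents)
    expect_equal(nrow(enumerate_candidates(s)), m * (m - 1) / 2)
  }
})

test_that("candidate instances export as JSON lines", {
  inst <- candidate_instances(table1_sentence())
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_instances_jsonl(inst, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$label, "Mechanism")
  expect_match(rec$text, "DRUG1")
})
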