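test_that("tokenizer covers words, numbers and digit/letter boundaries", {
  t1 <- tokenize("bupe 2 mg")
  expect_equal(t1$token, c("bupe", "2", "mg"))
  expect_equal(t1$start, c(0L, 5L, 7L))
  expect_equal(t1$end, c(4L, 6L, 9L))
  expect_equal(nrow(tokenize("")), 0L)
  t2 <- tokenize("100mcg")
  expect_equal(t2$token, c("100", "mcg"))
  expect_equal(t2$start, c(0L, 3L))
  expect_equal(t2$end, c(3L, 6L))
  t3 <- tokenize("U-47,700 now")
  expect_equal(t3$token, c("U", "47,700", "now"))
})

test_that("annotation maps slang and units to canonical concepts", {
  sp <- annotate("snorted some bupe last night", fixture_lex)
  expect_equal(nrow(sp), 2L)
  bupe <- sp[sp$surface == "bupe", ]
  expect_equal(bupe$concept_id, "Buprenorphine")
  expect_equal(bupe$term_type, "slang")
  route <- sp[sp$surface == "snorted", ]
  expect_equal(route$category, "route")

  sp2 <- annotate("took 2 mg", fixture_lex)
  expect_equal(sp2$canonical_label, "MILLIGRAM")

  # disabling routes drops the route span
  sp3 <- annotate("snorted some bupe", fixture_lex,
                  config = list(kinds = c("substance_class",
                                          "substance_instance")))
  expect_equal(sp3$surface, "bupe")
})

test_that("longest match wins over nested submatches", {
  sp <- annotate("furanyl fentanyl for sale", fixture_lex)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$concept_id, "Furanyl_Fentanyl")
  expect_equal(c(sp$start, sp$end), c(0L, 16L))
})

test_that("span invariants hold: surfaces index the raw text, no overlaps", {
  texts <- c(
    "injected 2 mg of bupe then took suboxone",
    "FENTANYL TRANSDERMAL PATCHES 100 mcg per h",
    "addicted to cannabis and feeling antsy",
    "u-47,700 powder and fuff 1 g"
  )
  for (txt in texts) {
    sp <- annotate(txt, fixture_lex)
    if (!nrow(sp)) next
    expect_true(all(sp$start >= 0 & sp$start < sp$end &
                      sp$end <= nchar(txt)))
    expect_equal(sp$surface, substring(txt, sp$start + 1L, sp$end))
    if (nrow(sp) > 1) {
      expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
    }
  }
})

test_that("annotator equals the brute-force all-window matcher", {
  withr::local_seed(20260919)
  for (i in seq_len(120)) {
    txt <- random_text(fixture_lex, n_tokens = sample(3:18, 1))
    got <- annotate(txt, fixture_lex)
    want <- brute_force_annotate(txt, fixture_lex)
    expect_equal(strip_spans(got), strip_spans(want), info = txt)
  }
})

test_that("case-sensitive market abbreviations only match their own case", {
  sp <- annotate("FE accepted here", fixture_lex)
  expect_true("Finalize_Early" %in% sp$concept_id)
  sp2 <- annotate("fe accepted here", fixture_lex)
  expect_false("Finalize_Early" %in% sp2$concept_id)
})

test_that("DSM-5 weak labeling counts matched lay terms per category", {
  r <- label_dsm5("feeling antsy and worried", fixture_lex)
  expect_equal(r$category_id, "Anxiety_Disorder")
  expect_equal(r$n_hits, 2L)

  r2 <- label_dsm5("addicted to cannabis", fixture_lex)
  expect_equal(r2$category_id, "Substance_Use_And_Addictive_Disorder")
  expect_equal(r2$n_hits, 1L)

  expect_equal(nrow(label_dsm5("hello world", fixture_lex)), 0L)
  # raising min_hits suppresses single-term evidence
  expect_equal(nrow(label_dsm5("addicted to cannabis", fixture_lex,
                               min_hits = 2)), 0L)
})

test_that("captured-concept counts are per distinct concept and complete", {
  corpus <- tibble::tibble(doc_id = "d1", text = "felt antsy today")
  cc <- count_captured_concepts(corpus, fixture_lex)
  expect_equal(cc$n_concepts[cc$category_id == "Anxiety_Disorder"], 1L)
  expect_true(all(cc$n_concepts[cc$category_id != "Anxiety_Disorder"] == 0L))

  empty <- count_captured_concepts(tibble::tibble(doc_id = character(),
                                                  text = character()),
                                   fixture_lex)
  expect_true(all(empty$n_concepts == 0L))

  # two distinct anxiety-category concepts: the lay term and the category
  corpus2 <- tibble::tibble(
    doc_id = c("d1", "d2"),
    text = c("so worried lately", "diagnosed with anxiety disorder")
  )
  cc2 <- count_captured_concepts(corpus2, fixture_lex)
  expect_equal(cc2$n_concepts[cc2$category_id == "Anxiety_Disorder"], 2L)
})

test_that("adding lexicon entries never removes existing spans", {
  txt <- "took bupe and some skag last night"
  before <- annotate(txt, fixture_lex)
  grown <- fixture_onto
  grown$terms <- dplyr::bind_rows(
    grown$terms,
    tibble::tibble(concept_id = "Heroin", surface = "skag",
                   term_type = "street", case_sensitive = FALSE)
  )
  grown <- dao_ontology(grown$concepts, grown$terms, grown$units,
                        grown$object_properties, grown$data_properties,
                        grown$annotations)
  after <- annotate(txt, compile_lexicon(grown))
  key <- function(sp) paste(sp$start, sp$end, sp$concept_id)
  expect_true(all(key(before) %in% key(after)))
  expect_true("skag" %in% after$surface)
})

test_that("standoff JSONL round-trips documents and spans", {
  docs <- tibble::tibble(
    doc_id = c("a", "b"),
    text = c("took 2 mg of bupe", "nothing here")
  )
  spans <- annotate_corpus(docs, fixture_lex)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_standoff_jsonl(docs, spans, f)
  back <- read_standoff_jsonl(f)
  expect_equal(back$docs, docs)
  expect_equal(nrow(back$spans), nrow(spans))
  expect_setequal(paste(back$spans$doc_id, back$spans$start, back$spans$end),
                  paste(spans$doc_id, spans$start, spans$end))
})
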