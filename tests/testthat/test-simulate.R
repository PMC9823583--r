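test_that("identical parameters and seed reproduce identical corpora", {
  p <- sim_params(n_docs = 20, seed = 7)
  c1 <- generate_forum_corpus(fixture_onto, p)
  c2 <- generate_forum_corpus(fixture_onto, p)
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$gold_spans, c2$gold_spans)

  l1 <- generate_listing_corpus(fixture_onto, sim_params(n_days = 5, seed = 7))
  l2 <- generate_listing_corpus(fixture_onto, sim_params(n_days = 5, seed = 7))
  expect_identical(l1$listings, l2$listings)
})

test_that("gold spans satisfy the span invariants against their documents", {
  corpus <- generate_forum_corpus(fixture_onto,
                                  sim_params(n_docs = 30, seed = 2,
                                             noise_rate = 0.05,
                                             distractor_rate = 0.3))
  for (i in seq_len(nrow(corpus$documents))) {
    doc <- corpus$documents[i, ]
    sp <- corpus$gold_spans[corpus$gold_spans$doc_id == doc$doc_id, ]
    expect_true(all(sp$start >= 0 & sp$start < sp$end &
                      sp$end <= nchar(doc$text)))
    # noise never mutates characters inside gold spans
    expect_equal(sp$surface, substring(doc$text, sp$start + 1L, sp$end))
  }
})

test_that("p_slang = 1 forces slang surfaces with canonical gold concepts", {
  corpus <- generate_forum_corpus(fixture_onto,
                                  sim_params(n_docs = 10, p_slang = 1,
                                             seed = 7))
  drugs <- corpus$gold_spans[
    !(corpus$gold_spans$category %in% c("unit", "route")), ]
  expect_true(all(drugs$term_type %in% c("slang", "street", "brand")))
  expect_true(all(drugs$concept_id %in% fixture_onto$concepts$id))
})

test_that("p_slang > 0 without slang-bearing substances is a parameter error", {
  bare <- dao_ontology(
    concepts = tibble::tibble(id = "Opioid", label = "opioid",
                              kind = "substance_class",
                              parent_id = NA_character_)
  )
  expect_error(
    generate_forum_corpus(bare, sim_params(n_docs = 1, p_slang = 0.5)),
    class = "dao_parameter_error"
  )
})

test_that("slang fraction concentrates around p_slang", {
  corpus <- generate_forum_corpus(fixture_onto,
                                  sim_params(n_docs = 1000, p_slang = 0.4,
                                             seed = 13))
  drugs <- corpus$gold_spans[
    !(corpus$gold_spans$category %in% c("unit", "route")), ]
  frac <- mean(drugs$term_type %in% c("slang", "street", "brand"))
  se <- sqrt(0.4 * 0.6 / nrow(drugs))
  expect_lt(abs(frac - 0.4), 3 * se)
})

test_that("listing volume follows the configured Poisson intensity", {
  corpus <- generate_listing_corpus(fixture_onto,
                                    sim_params(n_days = 30, lambda = 7,
                                               seed = 21))
  n <- nrow(corpus$listings)
  expect_lt(abs(n - 210), 3 * sqrt(210))
})

test_that("forced rate pattern marks every gold dosage as a rate", {
  corpus <- generate_listing_corpus(
    fixture_onto, sim_params(n_days = 5, lambda = 4, p_rate_pattern = 1,
                             seed = 5)
  )
  expect_true(all(corpus$listings$gold_dosage_is_rate))
  expect_true(all(grepl("mcg per h", corpus$listings$title)))
})

test_that("a single-vendor market summarizes to one unique vendor", {
  corpus <- generate_listing_corpus(
    fixture_onto, sim_params(n_days = 5, lambda = 4, n_vendors = 1, seed = 9)
  )
  rec <- parse_listings(corpus$listings, fixture_lex, fixture_onto)
  expect_equal(summarize_marketplace(rec)$n_vendors, 1L)
})

test_that("a gold corpus writes its documents, gold and parameters", {
  dir <- withr::local_tempdir()
  corpus <- generate_forum_corpus(fixture_onto,
                                  sim_params(n_docs = 5, seed = 3))
  write_gold_corpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "gold.jsonl")))
  expect_true(file.exists(file.path(dir, "params.json")))
  back <- read_standoff_jsonl(file.path(dir, "gold.jsonl"))
  expect_equal(back$docs, corpus$documents)
  params <- jsonlite::fromJSON(file.path(dir, "params.json"))
  expect_equal(params$seed, 3L)
  expect_equal(params$n_docs, 5L)
})
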