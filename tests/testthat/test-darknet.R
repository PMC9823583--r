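test_that("dosage normalization converts mass units to grams", {
  d <- normalize_dosage(100, "mcg per h")
  expect_equal(d$grams, 1e-4)
  expect_true(d$is_rate)

  d2 <- normalize_dosage(1, "g")
  expect_equal(d2$grams, 1)
  expect_false(d2$is_rate)

  d3 <- normalize_dosage(2, "oz")
  expect_equal(d3$grams, 56.699)
  expect_equal(normalize_dosage(1, "kg")$grams, 1000)
  expect_equal(normalize_dosage(1, "lb")$grams, 453.592)
  expect_equal(normalize_dosage(3, "mg")$grams, 0.003)
})

test_that("non-mass and unknown units raise typed errors", {
  units <- fixture_onto$units
  expect_error(normalize_dosage(1, "ml", units), class = "dao_dimension_error")
  expect_error(normalize_dosage(1, "parsec"), class = "dao_unknown_unit")
})

test_that("gram round trip through every mass unit is exact to 1e-9", {
  units <- mass_units()
  for (i in seq_len(nrow(units))) {
    for (g in c(1e-6, 0.003, 1, 28.3495, 453.592, 1234.5)) {
      value_in_unit <- g / units$to_grams[i]
      back <- normalize_dosage(value_in_unit,
                               units$surface_forms[[i]][1], units)$grams
      expect_lt(abs(back - g) / g, 1e-9)
    }
  }
})

test_that("the transdermal patch advertisement parses to its known record", {
  rec <- parse_listing("FENTANYL TRANSDERMAL PATCHES 100 mcg per h", "",
                       fixture_lex, fixture_onto)
  expect_equal(rec$substance_class, "fentanyl-type")
  expect_equal(rec$substance_name, "fentanyl")
  expect_equal(rec$dosage_value_g, 1e-4)
  expect_true(rec$dosage_is_rate)
  expect_equal(rec$form, "transdermal")
  expect_false(rec$unresolved)
})

test_that("cryptomarket abbreviations resolve; FE is never a substance", {
  rec <- parse_listing("fuff 1 g", "", fixture_lex, fixture_onto)
  expect_equal(rec$substance_id, "Fluoro_Furanyl_Fentanyl")
  expect_equal(rec$substance_class, "fentanyl-type")
  expect_equal(rec$dosage_value_g, 1)
  expect_false(rec$dosage_is_rate)

  fe <- parse_listing("HEROIN POWDER 1 g FE", "", fixture_lex, fixture_onto)
  expect_true(fe$finalize_early)
  expect_equal(fe$substance_id, "Heroin")

  none <- parse_listing("custom glassware", "", fixture_lex, fixture_onto)
  expect_true(none$unresolved)
  expect_true(is.na(none$substance_id))
})

test_that("substance falls back to the description when the title is bare", {
  rec <- parse_listing("great quality", "pressed oxycodone tablets 30 mg",
                       fixture_lex, fixture_onto)
  expect_equal(rec$substance_id, "Oxycodone")
  expect_equal(rec$form, "tablet")
  expect_equal(rec$dosage_value_g, 0.03)
})

test_that("daily averages are means over distinct crawl dates", {
  listings <- tibble::tibble(
    listing_id = sprintf("L%d", 1:8),
    market = "Agora",
    crawl_date = as.Date(c(rep("2015-03-01", 3), rep("2015-03-02", 5))),
    vendor_id = "v1",
    title = "FENTANYL POWDER 1 g",
    description = "",
    location = "US"
  )
  rec <- parse_listings(listings, fixture_lex, fixture_onto)
  agg <- aggregate_daily_averages(rec, fixture_onto)
  fent <- agg[agg$substance_type == "fentanyl", ]
  expect_equal(fent$mean_per_day, 4)     # (3 + 5) / 2 crawl dates
  expect_equal(fent$n_crawls, 2L)
  # substance types not advertised that month report zero, not absence
  her <- agg[agg$substance_type == "other opioids", ]
  expect_equal(her$mean_per_day, 0)
  expect_true(all(substance_type_rows(fixture_onto) %in% agg$substance_type))
})

test_that("per-type daily counts conserve the total of matched listings", {
  corpus <- generate_listing_corpus(fixture_onto,
                                    sim_params(n_days = 10, lambda = 5,
                                               seed = 3))
  rec <- parse_listings(corpus$listings, fixture_lex, fixture_onto)
  types <- substance_type_of(rec, fixture_onto)
  expect_false(any(is.na(types)))
  by_day <- table(rec$crawl_date)
  per_type_day <- tapply(seq_len(nrow(rec)),
                         list(as.character(rec$crawl_date), types), length)
  per_type_day[is.na(per_type_day)] <- 0
  expect_equal(rowSums(per_type_day), as.vector(by_day),
               ignore_attr = TRUE)
})

test_that("marketplace summaries report distinct counts", {
  listings <- tibble::tibble(
    listing_id = c("a", "b", "c"),
    market = "Dream",
    crawl_date = as.Date("2018-03-01"),
    vendor_id = "v9",
    title = c("HEROIN POWDER 1 g", "HEROIN POWDER 1 g",
              "CARFENTANIL 1 mg"),
    description = c("d1", "d1", "d2"),
    location = c("US", "US", "DE")
  )
  rec <- parse_listings(listings, fixture_lex, fixture_onto)
  s <- summarize_marketplace(rec)
  expect_equal(s$n_transactions, 3L)
  expect_equal(s$n_vendors, 1L)
  expect_equal(s$n_substances, 2L)
  expect_equal(s$n_locations, 2L)
  expect_equal(s$n_descriptions, 2L)
  expect_equal(nrow(summarize_marketplace(rec[0, ])), 0L)
})
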