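test_that("fixture ontology carries the expected term attachments", {
  te <- fixture_onto$terms
  bup <- te[te$concept_id == "Buprenorphine", ]
  expect_setequal(bup$surface[bup$term_type == "slang"], c("Bupe", "Bupey"))
  expect_setequal(bup$surface[bup$term_type == "brand"],
                  c("Suboxone", "Subutex"))

  tea <- fixture_onto$concepts[fixture_onto$concepts$id == "Poppy_Tea", ]
  expect_equal(tea$parent_id, "Morphine")
  expect_equal(tea$kind, "substance_instance")
  expect_setequal(te$surface[te$concept_id == "Poppy_Tea"],
                  c("Pod", "Poppy_Pods"))
})

test_that("fixture content counts are stable constants", {
  co <- fixture_onto$concepts
  # hand tally of the packaged term tables:
  # 32 substance classes + 1 instance + 3 forms + 3 preparations + 2 routes
  # + 20 DSM-5 categories + 4 mental-health terms = 65 concepts
  expect_equal(nrow(co), 65L)
  expect_equal(sum(co$kind == "substance_class"), 32L)
  expect_equal(sum(co$kind == "substance_instance"), 1L)
  expect_equal(sum(co$kind == "dsm5_category"), 20L)
  expect_equal(nrow(fixture_onto$terms), 22L)
  expect_equal(nrow(fixture_onto$units), 7L)
  # seven fentanyl analogs of the availability table plus the
  # cryptomarket-abbreviated fluoro-furanyl fentanyl
  analogs <- co$id[!is.na(co$parent_id) & co$parent_id == "Fentanyl_Type"]
  expect_length(setdiff(analogs, "Fentanyl"), 8L)
  expect_length(
    co$id[!is.na(co$parent_id) & co$parent_id == "Other_NP_Synthetic_Opioid"],
    9L
  )
})

test_that("fixture builder is deterministic and validates clean", {
  expect_identical(build_fixture_dao(), build_fixture_dao())
  expect_equal(nrow(validate_ontology(fixture_onto)), 0L)
})

test_that("validator reports cycles, dangling references and empty labels", {
  v <- validate_ontology(list(
    concepts = tibble::tibble(id = "A", label = "a", kind = "substance_class",
                              parent_id = "A"),
    terms = tibble::tibble(concept_id = "B", surface = "x",
                           term_type = "slang", case_sensitive = FALSE),
    units = tibble::tibble(id = character(), canonical_label = character(),
                           dimension = character(), to_grams = double(),
                           surface_forms = list()),
    annotations = tibble::tibble(subject_id = "C", property = "p",
                                 value = "v")
  ))
  expect_true("parent_cycle" %in% v$rule)
  expect_true("dangling_term_concept" %in% v$rule)
  expect_true("dangling_annotation_subject" %in% v$rule)

  v2 <- validate_ontology(list(
    concepts = tibble::tibble(id = "A", label = " ", kind = "substance_class",
                              parent_id = NA_character_),
    terms = tibble::tibble(concept_id = character(), surface = character(),
                           term_type = character(),
                           case_sensitive = logical()),
    units = tibble::tibble(id = character(), canonical_label = character(),
                           dimension = character(), to_grams = double(),
                           surface_forms = list()),
    annotations = tibble::tibble(subject_id = character(),
                                 property = character(), value = character())
  ))
  expect_true("empty_label" %in% v2$rule)
})

test_that("identical slang on sibling drugs is a warning-grade record", {
  onto <- toy_two_concept_ontology()
  v <- validate_ontology(onto)
  expect_true("duplicate_sibling_surface" %in% v$rule)
  expect_equal(v$severity[v$rule == "duplicate_sibling_surface"], "warning")
})

test_that("constructor refuses error-grade violations", {
  expect_error(
    dao_ontology(concepts = tibble::tibble(
      id = "A", label = "a", kind = "substance_class", parent_id = "Missing"
    )),
    class = "dao_integrity_error"
  )
})

test_that("substance-class resolution walks to the type level", {
  expect_equal(substance_class_of(fixture_onto, "Fentanyl"), "fentanyl-type")
  expect_equal(substance_class_of(fixture_onto, "Carfentanil"),
               "fentanyl-type")
  expect_equal(substance_class_of(fixture_onto, "Heroin"), "heroin")
  expect_equal(substance_class_of(fixture_onto, "Poppy_Tea"), "morphine")
  expect_equal(substance_class_of(fixture_onto, "U_47700"),
               "other NP synthetic opioids")
  # cross-check against a brute-force ancestor walk
  for (id in c("Fentanyl", "Carfentanil", "U_47700", "Poppy_Tea")) {
    chain <- id
    repeat {
      p <- fixture_onto$concepts$parent_id[
        match(chain[length(chain)], fixture_onto$concepts$id)]
      if (is.na(p)) break
      chain <- c(chain, p)
    }
    want <- if (length(chain) <= 2) chain[1] else chain[length(chain) - 1]
    expect_equal(
      substance_class_of(fixture_onto, id),
      fixture_onto$concepts$label[match(want, fixture_onto$concepts$id)]
    )
  }
})
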