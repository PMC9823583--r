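# Shared fixtures, computed once per test run.
fixture_onto <- build_fixture_dao()
fixture_lex <- compile_lexicon(fixture_onto)

# Independent oracle for the annotator: enumerate ALL token windows that
# match a lexicon entry, then resolve conflicts leftmost-first, longest
# (then term-type priority, then concept id) -- no incremental scanning.
brute_force_annotate <- function(text, lexicon) {
  toks <- tokenize(text)
  n <- nrow(toks)
  if (!n) {
    return(tibble::tibble(start = integer(), end = integer(),
                          concept_id = character()))
  }
  priority <- c(canonical = 1, brand = 2, street = 3, slang = 4, synonym = 5,
                abbreviation = 6, chemical_formula = 7, lay_term = 8)
  norm_tok <- function(x, keep_case = FALSE) {
    y <- if (keep_case) x else tolower(x)
    gsub("(?<=\\d),(?=\\d)", "", y, perl = TRUE)
  }
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      win <- toks$token[i:j]
      key_ci <- paste(norm_tok(win), collapse = " ")
      key_cs <- paste(norm_tok(win, TRUE), collapse = " ")
      hit <- which(
        (!lexicon$case_sensitive &
           tolower(lexicon$normalized_surface) == key_ci) |
          (lexicon$case_sensitive & lexicon$normalized_surface == key_cs)
      )
      for (h in hit) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = toks$start[i], end = toks$end[j],
          concept_id = lexicon$concept_id[h],
          pri = priority[[lexicon$term_type[h]]]
        )
      }
    }
  }
  if (!length(cand)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          concept_id = character()))
  }
  cand <- do.call(rbind, cand)
  out <- list()
  while (nrow(cand)) {
    s0 <- min(cand$start)
    at <- cand[cand$start == s0, , drop = FALSE]
    at <- at[at$end == max(at$end), , drop = FALSE]
    at <- at[at$pri == min(at$pri), , drop = FALSE]
    at <- at[order(at$concept_id), , drop = FALSE][1, ]
    out[[length(out) + 1L]] <- at
    cand <- cand[cand$start >= at$end | cand$end <= at$start, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  tibble::tibble(start = res$start, end = res$end,
                 concept_id = res$concept_id)
}

# Random short texts mixing lexicon surfaces, fillers and numbers.
random_text <- function(lexicon, n_tokens = 12) {
  surfaces <- sample(lexicon$normalized_surface,
                     min(40, nrow(lexicon)))
  fillers <- c("the", "and", "took", "some", "last", "night", "for", "sale",
               "good", "stuff", "cheap", "fast", "ship", "2", "10", "0.5")
  pool <- c(surfaces, fillers, fillers)
  paste(sample(pool, n_tokens, replace = TRUE), collapse = " ")
}

toy_two_concept_ontology <- function() {
  dao_ontology(
    concepts = tibble::tibble(
      id = c("Opioid", "DrugA", "DrugB"),
      label = c("opioid", "drug a", "drug b"),
      kind = "substance_class",
      parent_id = c(NA, "Opioid", "Opioid")
    ),
    terms = tibble::tibble(
      concept_id = c("DrugA", "DrugB"),
      surface = c("zip", "zip"),
      term_type = "slang",
      case_sensitive = FALSE
    )
  )
}

strip_spans <- function(sp) {
  data.frame(start = as.integer(sp$start), end = as.integer(sp$end),
             concept_id = as.character(sp$concept_id))
}
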