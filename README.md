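# daokit

Ontology-driven lexical annotation for substance-use text mining.

Public-health surveillance of nonmedical drug use increasingly relies on
web text — recovery-forum posts, social-media messages, and cryptomarket
advertisements — where substances are rarely called by their
pharmacological names. People write *bupe* for buprenorphine, *Pod* for
poppy-seed tea, *fuff* for fluoro-furanyl fentanyl. `daokit` provides a
self-contained toolkit for this setting, built around a drug-abuse ontology
(DAO): a class hierarchy of psychoactive substances whose concepts carry
brand names (`has_brand_name`), street and slang terms (`has_street_name`,
`has_slang_term`), chemical designations (`has_chemical_formula`), plus
units, dosage forms, routes of administration, and the 20 DSM-5 diagnostic
categories with lay-language terms (*antsy*, *worried*, "addicted to
cannabis").

The package is aimed at epidemiologists and computational social scientists
who need a transparent, rule-based alternative (or baseline) to learned
NER: every annotation is traceable to an ontology term, and every pipeline
stage is testable against a seeded synthetic gold corpus.

## What it does

- **Ontology model & I/O** — tidy-table ontology (`dao_ontology()`),
  a packaged mini-DAO fixture (`build_fixture_dao()`), canonical Turtle and
  RDF/XML serialization (`save_ontology()`, `load_ontology()`), structural
  validation (`validate_ontology()`).
- **Lexicon compiler** — `compile_lexicon()` turns the ontology into a
  deterministic surface-form index (normalized, pluralized, collision
  surfaces flagged ambiguous).
- **Annotator** — `annotate()` performs greedy leftmost-longest lexical
  lookup over token windows: `bupe → buprenorphine`, `mg → MILLIGRAM`;
  `label_dsm5()` weakly labels text with DSM-5 categories.
- **Triple extraction** — `extract_triples()` assembles sentence-local
  (drug, `has_dosage`, quantity+unit), (drug, `administered_via`, route)
  and co-mention triples by nearest-attachment rules.
- **Cryptomarket NER** — `parse_listing()` structures advertisement titles
  (substance, class, first dosage normalized to grams via
  `normalize_dosage()`, form, finalize-early flag);
  `aggregate_daily_averages()` and `summarize_marketplace()` reproduce the
  availability-table and marketplace-summary layouts.
- **Metrics & evaluation** — `compute_metrics()` counts axioms, classes,
  properties, individuals and assertions; `match_spans()` + `prf()` score
  predictions against standoff gold at exact or overlap criteria.
- **Synthetic gold corpora** — `generate_forum_corpus()` and
  `generate_listing_corpus()` emit seeded documents/listings with exact
  gold offsets and records, so precision and recall have a known truth.

The core matching contract: surfaces are normalized (lower-case,
underscores/hyphens to spaces, digit-grouping commas folded), and the
annotator returns non-overlapping spans chosen leftmost-first, longest
span winning, with offsets always indexing the raw text. Precision and
recall follow the usual definitions, reported on the percent scale:

    precision = 100 * tp / (tp + fp)      recall = 100 * tp / (tp + fn)

## Worked example

```r
library(daokit)

onto <- build_fixture_dao()
lex  <- compile_lexicon(onto)

annotate("snorted some bupe last night", lex)
#> # A tibble: 2 × 9
#>   doc_id start   end surface concept_id    canonical_label term_type category
#> 1 doc1       0     7 snorted Insufflation  insufflation    synonym   route
#> 2 doc1      13    17 bupe    Buprenorphine buprenorphine   slang     buprenorphine

ann <- annotate("injected 2 mg of bupe", lex)
extract_triples(ann, lex)
#>   doc_id sentence_index    subject_id        predicate object_id value  unit
#> 1 doc1                0 Buprenorphine       has_dosage MILLIGRAM     2  MILLIGRAM
#> 2 doc1                0 Buprenorphine administered_via Injection    NA  <NA>

parse_listing("FENTANYL TRANSDERMAL PATCHES 100 mcg per h", "", lex, onto)
#>   substance_id substance_name substance_class dosage_value_g dosage_is_rate
#> 1 Fentanyl     fentanyl       fentanyl-type            1e-04 TRUE
#>   dosage_unit  form        finalize_early unresolved
#> 1 MICROGRAM    transdermal  FALSE          FALSE
```

The slang term *bupe* resolves to the canonical buprenorphine concept; the
dosage phrase `2 mg` attaches to it as 2 MILLIGRAM; and the patch listing
normalizes `100 mcg per h` to `0.0001` grams per hour with class
`fentanyl-type` and form `transdermal`.

A command-line wrapper over the same functions ships at
`inst/cli/daokit.R` (subcommands `build-fixture`, `compile-lexicon`,
`annotate`, `triples`, `parse-listings`, `aggregate`, `metrics`,
`evaluate`, `simulate`).

## Documentation

The methods vignette (`vignettes/dao-annotation-methods.Rmd`) describes
the ontology model, the matching and attachment rules, the generator's
design and its limits, and the package's numerical choices.
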