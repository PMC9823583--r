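---
title: "Methods: ontology-driven annotation of substance-use text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven annotation of substance-use text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daokit)
```

## The problem and the model

Substance-use discussions on the open and dark web use a vocabulary that
standard medical terminologies do not cover: slang and street names
(*bupe*, *Pod*), brand names (Suboxone, Duragesic), market abbreviations
(*fuff*), and lay mental-health language (*antsy*, "addicted to
cannabis"). `daokit` treats this vocabulary problem as an ontology
problem. An ontology here is a validated bundle of tidy tables:

* a concept hierarchy — substance classes and instances, dosage forms,
  preparation practices, routes of administration, DSM-5 diagnostic
  categories and mental-health terms;
* term attachments — surface strings tied to concepts through typed
  data properties (`has_brand_name`, `has_street_name`, `has_slang_term`,
  `has_synonym`, `has_chemical_formula`, `has_abbreviation`,
  `has_lay_term`);
* unit concepts with surface forms, a dimension, and (for mass units) a
  gram-conversion factor;
* declared property names and free annotation triples.

Everything downstream — annotation, triple extraction, listing parsing,
metrics — is a pure function of this bundle, which is what makes the
pipeline auditable: every produced span can be traced to one table row.

The packaged fixture (`build_fixture_dao()`) instantiates the model with
an opioid class (buprenorphine and its brands/slang; fentanyl with its
analogs and the abbreviated fluoro-furanyl fentanyl; nonpharmaceutical
synthetic opioids such as U-47,700; heroin, morphine with the Poppy Tea
instance, loperamide, methadone and common pharmaceutical opioids), a
cannabinoid class with a synthetic-cannabinoid subtype, units, forms,
routes, and the 20 DSM-5 categories with a small set of lay terms. Its
content counts are fixed constants of the package, asserted in tests; the
fixture makes no claim to reproduce any external ontology's counts.

Two modelling choices deserve a note. First, brand names are modelled as
term attachments *of* the substance (Suboxone is a brand name of
buprenorphine), not as super- or subclasses; this keeps the class
hierarchy purely pharmacological. Second, the cryptomarket transaction
term FE ("finalize early") is not a substance and has no natural home in
the concept-kind enumeration; it is carried as a preparation-kind concept
whose only role is that the listing parser maps any match of its
case-sensitive abbreviation to a `finalize_early` flag and never to a
substance or form field.

## Serialization

Ontologies serialize to RDF in two dialects. Turtle output is *canonical*:
a fixed prefix block followed by one triple per line in byte-sorted
(C-locale) order. Canonicalization buys two properties the tests rely on:
equal ontologies produce byte-identical files, and save → load → save is a
byte-identity. RDF/XML (via `xml2`) is provided for interchange with
OWL tooling and round-trips through the same internal triple table.
Properties outside the package vocabulary are preserved as annotation
triples on load rather than dropped. Term case-sensitivity, which RDF
literals cannot express directly, is carried by a companion
`term_case_sensitive` annotation triple.

## Lexicon compilation and matching

`compile_lexicon()` produces one entry per canonical concept label, per
term attachment and per unit surface form. Normalization lower-cases
(unless an entry is case-sensitive), folds underscores, hyphens and commas
to spaces, removes digit-grouping commas, splits digit/letter boundaries,
and strips trailing punctuation — exactly mirroring the tokenizer, so a
display form like `Poppy_Tea` or a table-printed code like `U-47,700`
folds to the token sequence it will produce in running text. Naive
s-plurals are added for word-like surfaces; unit symbols are never
pluralized (their plural spellings are listed explicitly), and surfaces
whose final token has at most two characters or contains a digit are
treated as symbols. A surface attached to more than one concept is marked
ambiguous on every entry; ambiguity is surfaced, not resolved, because the
right disambiguation policy is corpus-dependent. A configurable risky-
surface list (default: `pod`) flags short surfaces that double as common
English words.

`annotate()` is a greedy leftmost-longest matcher over normalized token
windows: at each token position the longest matching window becomes a
span and matching resumes after it. Ties at equal length break by
term-type priority (canonical > brand > street > slang > synonym >
abbreviation > chemical formula > lay term), then by concept id, making
the output deterministic. Offsets are 0-based half-open indexes into the
raw text; normalization is applied to candidate windows only, never to
stored offsets. The test suite certifies this scanner against an
independent oracle that enumerates *all* matching token windows and
resolves conflicts explicitly.

DSM-5 labeling (`label_dsm5()`) is deliberately weak supervision: every
matched DSM-5 concept or lay term rolls up to its diagnostic category, and
a category is reported when at least `min_hits` terms matched. The default
`min_hits = 1` is the weakest sensible threshold; raising it trades recall
for precision when single lay terms (e.g. *worried*) are too noisy for a
corpus.

## Triple extraction

Within each sentence (terminal punctuation with an abbreviation
stop-list), attachment is by character distance: a numeric literal
immediately preceding a unit span forms a quantity, which attaches to the
nearest *preceding* substance span, falling back to the nearest following
one — the pattern "injected 2 mg of bupe" puts the dose before the drug,
so a following-substance fallback is required. Routes and forms attach to
the nearest substance with ties broken toward the preceding span, and
distinct substances in one sentence are recorded as co-mentions. These
rules are heuristics, not parsing; they are exact on the template
structures the generator emits and approximate on free text.

## Cryptomarket listings

`parse_listing()` resolves the substance as the longest match in the
title, falling back to the description; its reporting class is the
ancestor one level below the pharmacological root, so fentanyl and every
analog report as the *fentanyl-type* class while heroin (a direct child of
the opioid root) is its own class. Dosage is the first quantity +
mass-unit match, normalized to grams (mcg/µg/ug 1e-6, mg 1e-3, g 1,
kg 1e3, oz 28.3495, lb 453.592), with a per-hour suffix (`per h`, `/hr`)
setting a rate flag — patch strengths such as `100 mcg per h` normalize to
`1e-4` g/h. Listings without a substance match are flagged `unresolved`
and retained, so denominators remain visible.

`aggregate_daily_averages()` reports, per market and calendar month, the
mean over distinct crawl dates of daily listing counts by substance-type
row ("fentanyl" including pharmaceutical mentions, one row per analog, one
per nonpharmaceutical synthetic opioid, "other opioids" excluding
pharmaceutical fentanyl). Days without a crawl are excluded from the
denominator (averages are per crawl-day); rows absent on a crawl day
contribute zeros, so every reporting row appears in every market-month. A
listing contributes to the row of its matched substance; multi-substance
listings would count once per matched row, a choice documented here
because published tables rarely state it.

## The synthetic gold corpus

The generator exists so that every stage has a ground truth. Forum posts
are template-built — `"i <route> <qty> <unit> of <drug-surface>
<fillers>."` — with the drug surface drawn from slang/street/brand
attachments with probability `p_slang` (default 0.4, a realistic mix for
recovery-forum text where informal names dominate but canonical names
still occur), a dosage phrase with probability `p_unit` (0.7) and a route
with probability `p_route` (0.6). Listings are drawn per market and day
from a Poisson(λ = 7) count over 30 days — a small-cryptomarket scale that
keeps test runtimes in seconds while giving the mean-recovery checks
adequate power — with the patch-strength title pattern at probability 0.3.

Noise is character substitution only, applied *outside* gold spans at a
per-character rate; this keeps gold offsets valid by construction, which
is the property the evaluation depends on. Distractor words are
pseudo-drug strings absent from the ontology. What the generator does
**not** emulate: misspelled drug mentions (noise never touches gold
spans), creative or emerging slang outside the ontology, code-switching,
sarcasm, multi-sentence discourse structure, or adversarial vendor
obfuscation. Perfect scores on the noise-free corpus therefore certify the
*mechanics* (offset arithmetic, normalization symmetry, longest-match
resolution, unit conversion) — they say nothing about recall on real
text, which is bounded by ontology coverage.

All generation runs on a single seeded RNG stream; identical parameters
and seed reproduce byte-identical corpora.

## Evaluation

`match_spans()` pairs predictions to gold greedily in span order, each
gold consuming at most one prediction, under an `exact` criterion (same
start, end and concept) or an `overlap` criterion (any character overlap,
same concept). Exact is the default because it is the strictest and fully
reproducible; overlap exists for sensitivity analysis. Precision, recall
and F1 are reported on the percent scale; degenerate confusions (empty
denominators) report zeros with a flag rather than NaN.

## Ontology metrics

`compute_metrics()` counts declaration axioms (one per declared class —
units included, as dosage classes — individual, and property), logical
axioms (subclass links, class assertions, data-property assertions for
term attachments and unit surface forms), and annotation assertions;
built-in OWL entities are not counted unless explicitly declared. The
counts obey a delta law — adding an instance with *d* term attachments
raises the individual count by 1, class assertions by 1, data-property
assertions by *d*, and the combined axiom count by 2 + *d* — which the
suite property-tests under hundreds of random insertions.

## Numerical and scale choices

Gram factors are exact decimals except the ounce (28.3495) and pound
(453.592), stored at the precision conventionally printed; unit round
trips are asserted to a relative 1e-9, which is the honest tolerance for
double-precision multiplication and division. Canonical Turtle sorts with
radix (C-locale) ordering to be independent of the session locale.
Problem sizes in the test suite — 500 random texts for the oracle
equivalence, 200 noise-free posts, 30 × Poisson(7) listings, 200 metric
insertions — were chosen so each property has clear statistical power
(binomial and Poisson checks use 3-standard-error bands) while the whole
suite stays fast enough to run habitually.

## Known limitations

* Recall is bounded by ontology coverage; the matcher has no fuzzy or
  embedding-based fallback by design.
* Ambiguous surfaces are flagged, not disambiguated.
* Sentence splitting and nearest-attachment are heuristics; clause-level
  scope (negation, reported speech) is out of scope.
* The RDF reader targets the package's own vocabulary profile (plus
  arbitrary annotation properties); it is not a general OWL reasoner.
* Listing parsing extracts the first dosage only; multi-pack quantities
  ("10 x 1 mg") are recorded per unit dose.
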