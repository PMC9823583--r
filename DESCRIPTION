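Package: daokit
Title: Ontology-Driven Lexical Annotation for Substance-Use Text Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for ontology-driven surveillance of
    substance-use discussions in web text. Provides a tabular ontology model
    for psychoactive-substance concepts with brand, street, slang and
    chemical-formula term attachments plus unit, form, route and DSM-5
    mental-health concepts; Turtle and RDF/XML serialization; a deterministic
    lexicon compiler; a longest-match lexical annotator with unit and slang
    normalization; sentence-local triple extraction (drug-dosage, drug-route);
    a cryptomarket-listing named-entity recognizer with dosage normalization
    to grams and availability aggregation; ontology structural metrics;
    span-level precision/recall evaluation; and seeded synthetic forum and
    listing corpora with gold annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    xml2
Suggests:
    callr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
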