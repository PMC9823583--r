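#' Normalize a surface form for lexical lookup
#'
#' Folds a display form (as stored in the ontology or appearing in running
#' text) to the canonical matching form: lower-cased, underscores and
#' hyphens replaced by spaces, digit-grouping commas removed (so
#' `"U-47,700"` and `"U-47700"` fold together), remaining commas treated as
#' separators, runs of whitespace collapsed to a single space, and
#' leading/trailing whitespace and trailing punctuation stripped.
#'
#' @param term Character vector of surface forms.
#' @param keep_case Keep letter case (used for case-sensitive entries such
#'   as the market abbreviation `FE`).
#' @return Character vector of normalized forms.
#' @examples
#' normalize_surface("Poppy_Tea")     # "poppy tea"
#' normalize_surface("  Bupe, ")      # "bupe"
#' normalize_surface("U-47,700")      # "u 47700"
#' @export
normalize_surface <- function(term, keep_case = FALSE) {
  x <- as.character(term)
  if (!keep_case) x <- tolower(x)
  x <- gsub("(?<=\\d),(?=\\d)", "", x, perl = TRUE)
  x <- gsub("[_,-]", " ", x)
  # split digit/letter boundaries the same way the tokenizer does, so
  # chemical codes like U-4TDP fold to the token sequence they produce
  x <- gsub("(?<=[0-9])(?=[A-Za-z])", " ", x, perl = TRUE)
  x <- gsub("(?<=[A-Za-z])(?=[0-9])", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  x <- sub("[[:punct:]]+$", "", x)
  trimws(x)
}

#' Expand naive surface variants of a term
#'
#' Returns the normalized surface plus a naive s-plural. Symbol-like
#' surfaces (final token of one or two characters, or containing a digit)
#' are not pluralized, and unit surface forms are never pluralized at
#' compile time (their plural spellings are listed explicitly), keeping the
#' matcher deterministic and auditable.
#'
#' @param term A single surface form.
#' @return Character vector of deduplicated normalized variants.
#' @examples
#' expand_variants("poppy pod")  # "poppy pod" "poppy pods"
#' expand_variants("mg")         # "mg"
#' @export
expand_variants <- function(term) {
  base <- normalize_surface(term)
  if (!nzchar(base)) return(character())
  out <- base
  last <- utils::tail(strsplit(base, " ", fixed = TRUE)[[1]], 1)
  symbolic <- nchar(last) <= 2L || grepl("\\d", last)
  if (!symbolic && !grepl("s$", base)) out <- c(out, paste0(base, "s"))
  unique(out)
}

token_count <- function(x) {
  lengths(strsplit(x, " ", fixed = TRUE))
}

default_lexicon_config <- function() {
  list(
    plural_variants = TRUE,
    # short surfaces that double as common strings; flagged ambiguous so
    # downstream consumers can drop or audit them
    risky_surfaces = c("pod"),
    include_canonical = TRUE
  )
}

#' Compile an ontology into a surface-form lexicon
#'
#' Produces one entry per canonical concept label, one per term attachment
#' (brand, street, slang, synonym, abbreviation, chemical formula, lay
#' term), and one per unit surface form, each mapped to its concept with
#' its substance-type class (see [substance_class_of()]) or concept kind as
#' `category`. Naive s-plural variants are added for non-symbolic surfaces.
#' A surface attached to more than one concept is marked `ambiguous` on
#' every entry, as are configured risky short surfaces. Compilation is a
#' pure function of the ontology and config: the same input yields an
#' identical lexicon with an identical source digest.
#'
#' @param ontology A validated `dao_ontology`.
#' @param config List of options; see `default_lexicon_config()`:
#'   `plural_variants` (logical), `risky_surfaces` (character),
#'   `include_canonical` (logical).
#' @return A tibble of class `dao_lexicon` with columns
#'   `normalized_surface`, `token_length`, `concept_id`, `term_type`,
#'   `category`, `case_sensitive`, `ambiguous`, plus attributes
#'   `max_token_length` and `source_ontology_digest`.
#' @examples
#' lex <- compile_lexicon(build_fixture_dao())
#' dplyr::filter(lex, normalized_surface == "bupe")
#' @export
compile_lexicon <- function(ontology, config = default_lexicon_config()) {
  config <- utils::modifyList(default_lexicon_config(), config)
  co <- ontology$concepts
  rows <- list()

  category_of <- function(concept_id) {
    kind <- co$kind[match(concept_id, co$id)]
    vapply(seq_along(concept_id), function(i) {
      k <- kind[i]
      if (k %in% c("substance_class", "substance_instance")) {
        substance_class_of(ontology, concept_id[i])
      } else if (k %in% c("dsm5_category", "mental_health_term")) {
        anc <- concept_ancestors(ontology, concept_id[i])
        chain <- c(concept_id[i], anc)
        kinds <- co$kind[match(chain, co$id)]
        cat_id <- chain[kinds == "dsm5_category"]
        if (length(cat_id)) utils::tail(cat_id, 1) else concept_id[i]
      } else {
        k
      }
    }, character(1))
  }

  add_entry <- function(surface, concept_id, term_type, case_sensitive,
                        pluralize = TRUE) {
    norm <- normalize_surface(surface, keep_case = case_sensitive)
    if (!nzchar(norm)) return()
    variants <- if (isTRUE(config$plural_variants) && !case_sensitive &&
                      pluralize) {
      expand_variants(norm)
    } else {
      norm
    }
    rows[[length(rows) + 1L]] <<- tibble(
      normalized_surface = variants,
      concept_id = concept_id,
      term_type = term_type,
      case_sensitive = case_sensitive
    )
  }

  if (isTRUE(config$include_canonical)) {
    for (i in seq_len(nrow(co))) {
      add_entry(co$label[i], co$id[i], "canonical", FALSE)
    }
  }
  te <- ontology$terms
  for (i in seq_len(nrow(te))) {
    add_entry(te$surface[i], te$concept_id[i], te$term_type[i],
              isTRUE(te$case_sensitive[i]))
  }
  un <- ontology$units
  for (i in seq_len(nrow(un))) {
    for (sf in un$surface_forms[[i]]) {
      add_entry(sf, un$id[i], "canonical", FALSE, pluralize = FALSE)
    }
  }

  entries <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    normalized_surface = character(), concept_id = character(),
    term_type = character(), case_sensitive = logical()
  )
  entries <- dplyr::distinct(entries)
  entries$token_length <- token_count(entries$normalized_surface)

  cat <- character(nrow(entries))
  is_unit <- entries$concept_id %in% un$id
  cat[is_unit] <- "unit"
  if (any(!is_unit)) cat[!is_unit] <- category_of(entries$concept_id[!is_unit])
  entries$category <- cat
  entries$kind <- ifelse(
    is_unit, "unit", co$kind[match(entries$concept_id, co$id)]
  )
  entries$canonical_label <- ifelse(
    is_unit,
    un$canonical_label[match(entries$concept_id, un$id)],
    co$label[match(entries$concept_id, co$id)]
  )

  match_key <- ifelse(entries$case_sensitive, entries$normalized_surface,
                      tolower(entries$normalized_surface))
  n_concepts <- tapply(entries$concept_id, match_key,
                       function(x) length(unique(x)))
  entries$ambiguous <- as.vector(n_concepts[match_key]) > 1L |
    tolower(entries$normalized_surface) %in%
      tolower(config$risky_surfaces %||% character())

  entries <- entries[order(entries$normalized_surface, entries$concept_id,
                           entries$term_type, method = "radix"), , drop = FALSE]
  entries <- entries[, c("normalized_surface", "token_length", "concept_id",
                         "canonical_label", "term_type", "kind", "category",
                         "case_sensitive", "ambiguous")]
  structure(
    as_tibble(entries),
    max_token_length = if (nrow(entries)) max(entries$token_length) else 0L,
    source_ontology_digest = ontology_digest(ontology),
    class = c("dao_lexicon", class(as_tibble(entries)))
  )
}

#' @export
print.dao_lexicon <- function(x, ...) {
  cat("<dao_lexicon> ", nrow(x), " entries, max token length ",
      attr(x, "max_token_length"), ", source digest ",
      substr(attr(x, "source_ontology_digest"), 1, 8), "\n", sep = "")
  NextMethod()
}

#' Export / import a lexicon as JSONL
#'
#' One JSON object per line, for inspection and diffing. Importing restores
#' the `dao_lexicon` attributes from the sidecar header line.
#'
#' @param lexicon A `dao_lexicon`.
#' @param path File path.
#' @return `write_lexicon_jsonl()` returns `path` invisibly;
#'   `read_lexicon_jsonl()` returns a `dao_lexicon`.
#' @export
write_lexicon_jsonl <- function(lexicon, path) {
  header <- jsonlite::toJSON(
    list(max_token_length = attr(lexicon, "max_token_length"),
         source_ontology_digest = attr(lexicon, "source_ontology_digest")),
    auto_unbox = TRUE
  )
  body <- vapply(seq_len(nrow(lexicon)), function(i) {
    as.character(jsonlite::toJSON(as.list(lexicon[i, ]), auto_unbox = TRUE))
  }, character(1))
  writeLines(c(as.character(header), body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lexicon_jsonl
#' @export
read_lexicon_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  rows <- lapply(lines[-1], function(l) as_tibble(jsonlite::fromJSON(l)))
  entries <- dplyr::bind_rows(rows)
  structure(
    entries,
    max_token_length = header$max_token_length,
    source_ontology_digest = header$source_ontology_digest,
    class = c("dao_lexicon", class(entries))
  )
}

# Fast lookup structure: environment keyed by match key -> row indices.
lexicon_index <- function(lexicon) {
  key <- ifelse(lexicon$case_sensitive, lexicon$normalized_surface,
                tolower(lexicon$normalized_surface))
  split(seq_len(nrow(lexicon)), key)
}
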