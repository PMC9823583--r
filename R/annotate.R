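term_type_priority <- c(
  canonical = 1, brand = 2, street = 3, slang = 4, synonym = 5,
  abbreviation = 6, chemical_formula = 7, lay_term = 8
)

#' Tokenize text with character offsets
#'
#' Splits text into maximal word tokens: letter runs (with apostrophes),
#' and number literals (digit runs with optional digit-grouping commas and
#' a decimal part). A digit/letter boundary splits, so `"100mcg"` yields
#' the tokens `100` and `mcg`. Offsets are 0-based half-open indexes into
#' the original string.
#'
#' @param text A single string.
#' @return Tibble with columns `token`, `start`, `end`.
#' @examples
#' tokenize("bupe 2 mg")
#' tokenize("100mcg")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[\\p{L}']+|[0-9]+(?:,[0-9]{3})*(?:\\.[0-9]+)?", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble(
    token = substring(text, start + 1L, start + len),
    start = start,
    end = start + as.integer(len)
  )
}

# token-level fold applied to candidate windows before lookup
normalize_token <- function(token, keep_case = FALSE) {
  x <- if (keep_case) token else tolower(token)
  gsub("(?<=\\d),(?=\\d)", "", x, perl = TRUE)
}

default_annotate_config <- function() {
  list(drop_ambiguous = FALSE, kinds = NULL)
}

empty_spans <- function() {
  tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), concept_id = character(),
    canonical_label = character(), term_type = character(),
    category = character(), ambiguous = logical()
  )
}

pick_best_entry <- function(lexicon, rows) {
  if (length(rows) == 1L) return(rows)
  pri <- term_type_priority[lexicon$term_type[rows]]
  rows <- rows[pri == min(pri)]
  if (length(rows) > 1L) rows <- rows[order(lexicon$concept_id[rows])]
  rows[1]
}

#' Annotate text with ontology concepts
#'
#' Greedy leftmost-longest lexical lookup over normalized token windows: at
#' each position the longest window whose normalized form is in the lexicon
#' becomes a span, slang and street forms map to their canonical concept
#' (bupe to buprenorphine), and unit surfaces map to canonical unit labels
#' (mg to MILLIGRAM). Spans never overlap; offsets always index the raw,
#' un-normalized text. Ties at equal span length are broken by term-type
#' priority (canonical over brand over street over slang over synonym over
#' abbreviation over chemical formula over lay term), then concept id.
#' Surfaces attached to several concepts are emitted with `ambiguous = TRUE`
#' (or dropped when `config$drop_ambiguous`).
#'
#' @param text A single string.
#' @param lexicon A `dao_lexicon` from [compile_lexicon()].
#' @param config List: `drop_ambiguous` (logical), `kinds` (optional
#'   character vector restricting matched concept kinds, e.g. exclude
#'   `"route"` when route annotation is disabled).
#' @param doc_id Document identifier carried into the output.
#' @return A tibble of entity spans (class `dao_annotations`) with columns
#'   `doc_id`, `start`, `end`, `surface`, `concept_id`, `canonical_label`,
#'   `term_type`, `category`, `ambiguous`; attributes `text` and
#'   `lexicon_digest`.
#' @examples
#' lex <- compile_lexicon(build_fixture_dao())
#' annotate("snorted some bupe last night", lex)
#' @export
annotate <- function(text, lexicon, config = default_annotate_config(),
                     doc_id = "doc1") {
  config <- utils::modifyList(default_annotate_config(), config)
  lex <- lexicon
  if (!is.null(config$kinds)) {
    keep <- lex$kind %in% config$kinds
    lex <- lex[keep, , drop = FALSE]
  }
  if (isTRUE(config$drop_ambiguous)) {
    lex <- lex[!lex$ambiguous, , drop = FALSE]
  }
  idx <- lexicon_index(lex)
  max_len <- if (nrow(lex)) max(lex$token_length) else 0L

  toks <- tokenize(text)
  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (L < 1L) break
      j <- i + L - 1L
      win <- toks$token[i:j]
      key_ci <- paste(normalize_token(win), collapse = " ")
      key_cs <- paste(normalize_token(win, keep_case = TRUE), collapse = " ")
      rows <- c(
        idx[[key_ci]][!lex$case_sensitive[idx[[key_ci]]]],
        idx[[key_cs]][lex$case_sensitive[idx[[key_cs]]]]
      )
      if (length(rows)) {
        r <- pick_best_entry(lex, rows)
        out[[length(out) + 1L]] <- tibble(
          doc_id = doc_id,
          start = toks$start[i], end = toks$end[j],
          surface = substring(text, toks$start[i] + 1L, toks$end[j]),
          concept_id = lex$concept_id[r],
          canonical_label = lex$canonical_label[r],
          term_type = lex$term_type[r],
          category = lex$category[r],
          ambiguous = lex$ambiguous[r]
        )
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  spans <- if (length(out)) dplyr::bind_rows(out) else empty_spans()
  structure(
    spans,
    text = text,
    lexicon_digest = attr(lexicon, "source_ontology_digest"),
    class = c("dao_annotations", class(spans))
  )
}

#' Annotate a corpus of documents
#'
#' @param docs Data frame with columns `doc_id` and `text`.
#' @param lexicon A `dao_lexicon`.
#' @param config See [annotate()].
#' @return A tibble of spans across all documents.
#' @export
annotate_corpus <- function(docs, lexicon,
                            config = default_annotate_config()) {
  out <- purrr::map2(docs$doc_id, docs$text, function(id, txt) {
    as_tibble(annotate(txt, lexicon, config, doc_id = id))
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) res <- empty_spans()
  res
}

dsm5_kinds <- c("dsm5_category", "mental_health_term")

#' Weakly label text with DSM-5 categories
#'
#' Annotates the text and rolls every matched DSM-5 concept or
#' mental-health lay term up to its DSM-5 diagnostic category; a category
#' is reported when at least `min_hits` of its terms matched.
#'
#' @param text A single string.
#' @param lexicon A `dao_lexicon` compiled from an ontology with DSM-5
#'   categories and lay terms.
#' @param min_hits Minimum number of term matches for a category label
#'   (default 1, the weakest supervision).
#' @return Tibble with columns `category_id`, `n_hits`.
#' @examples
#' lex <- compile_lexicon(build_fixture_dao())
#' label_dsm5("feeling antsy and worried", lex)
#' @export
label_dsm5 <- function(text, lexicon, min_hits = 1L) {
  spans <- annotate(text, lexicon)
  spans <- spans[lexicon_kind_of(lexicon, spans$concept_id) %in% dsm5_kinds, ,
                 drop = FALSE]
  if (!nrow(spans)) {
    return(tibble(category_id = character(), n_hits = integer()))
  }
  out <- dplyr::count(as_tibble(spans), .data$category, name = "n_hits")
  out <- dplyr::rename(out, category_id = "category")
  dplyr::filter(out, .data$n_hits >= min_hits)
}

lexicon_kind_of <- function(lexicon, concept_id) {
  lexicon$kind[match(concept_id, lexicon$concept_id)]
}

#' Count distinct DSM-5 concepts captured in a corpus
#'
#' For each DSM-5 category, counts the number of distinct ontology concepts
#' (categories themselves or mental-health terms) matched anywhere in the
#' corpus. Adding lay/slang attachments to the lexicon can only keep or
#' increase these counts.
#'
#' @param corpus Data frame with columns `doc_id`, `text`.
#' @param lexicon A `dao_lexicon`.
#' @return Tibble with columns `category_id`, `n_concepts`, one row per
#'   DSM-5 category known to the lexicon (zeros included).
#' @export
count_captured_concepts <- function(corpus, lexicon) {
  cats <- sort(unique(lexicon$category[lexicon$kind %in% dsm5_kinds]))
  base <- tibble(category_id = cats, n_concepts = 0L)
  if (!nrow(corpus)) return(base)
  spans <- annotate_corpus(corpus, lexicon)
  spans <- spans[lexicon_kind_of(lexicon, spans$concept_id) %in% dsm5_kinds, ,
                 drop = FALSE]
  if (!nrow(spans)) return(base)
  got <- dplyr::summarise(
    dplyr::group_by(spans, category_id = .data$category),
    n_concepts = dplyr::n_distinct(.data$concept_id), .groups = "drop"
  )
  out <- dplyr::rows_update(base, got, by = "category_id")
  out
}

#' Write / read standoff annotations as JSONL
#'
#' One document per line: `{"doc_id": ..., "text": ..., "spans": [...]}`.
#'
#' @param docs Data frame with columns `doc_id`, `text`.
#' @param spans Span tibble as returned by [annotate_corpus()].
#' @param path File path.
#' @return `write_standoff_jsonl()` returns `path` invisibly;
#'   `read_standoff_jsonl()` returns a list with tibbles `docs` and `spans`.
#' @export
write_standoff_jsonl <- function(docs, spans, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    id <- docs$doc_id[i]
    sp <- spans[spans$doc_id == id, setdiff(names(spans), "doc_id"),
                drop = FALSE]
    as.character(jsonlite::toJSON(
      list(doc_id = id, text = docs$text[i], spans = sp),
      auto_unbox = TRUE, digits = NA
    ))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_standoff_jsonl
#' @export
read_standoff_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list(); spans <- list()
  for (l in lines) {
    obj <- jsonlite::fromJSON(l)
    docs[[length(docs) + 1L]] <- tibble(doc_id = obj$doc_id, text = obj$text)
    sp <- as_tibble(obj$spans)
    if (nrow(sp)) {
      sp$doc_id <- obj$doc_id
      spans[[length(spans) + 1L]] <- sp
    }
  }
  sp <- dplyr::bind_rows(spans)
  if (nrow(sp)) sp <- dplyr::relocate(sp, "doc_id")
  list(docs = dplyr::bind_rows(docs), spans = sp)
}
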