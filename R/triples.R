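default_sentence_abbrevs <- c("dr", "mr", "mrs", "ms", "e.g", "i.e", "eg",
                              "ie", "vs", "etc", "approx", "no", "st")

#' Split text into sentence spans
#'
#' Sentences end at runs of terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace or end of text, except after a stop-listed abbreviation
#' ("Dr.", "e.g."). Returned spans are 0-based half-open and cover the
#' whole text.
#'
#' @param text A single string.
#' @param abbrevs Lower-case abbreviation stop-list (without the final dot).
#' @return Tibble with columns `start`, `end`, `sentence_index`.
#' @examples
#' split_sentences("I took bupe. It worked.")
#' @export
split_sentences <- function(text, abbrevs = default_sentence_abbrevs) {
  n <- nchar(text)
  if (n == 0L) {
    return(tibble(start = integer(), end = integer(),
                  sentence_index = integer()))
  }
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L # 1-based last punct
    for (e in ends) {
      before <- substring(text, 1L, as.integer(e) - 1L)
      word <- tolower(sub(".*?([A-Za-z.]+)$", "\\1", before))
      word <- sub("\\.$", "", word)
      if (word %in% abbrevs) next
      cuts <- c(cuts, as.integer(e)) # sentence ends after punctuation
    }
  }
  bounds <- unique(c(cuts[cuts < n], n))
  start <- c(0L, bounds[-length(bounds)])
  tibble(start = start, end = bounds,
         sentence_index = seq_along(bounds) - 1L)
}

substance_kinds <- c("substance_class", "substance_instance")

# numeric literal (with optional decimal part) immediately preceding a span
preceding_quantity <- function(text, span_start) {
  before <- substring(text, 1L, span_start)
  m <- regexec("([0-9]+(?:\\.[0-9]+)?)\\s*$", before)[[1]]
  if (m[1] == -1L) return(NULL)
  val <- regmatches(before, list(m))[[1]][2]
  list(value = as.numeric(val), start = as.integer(m[2]) - 1L)
}

empty_triples <- function() {
  tibble(
    doc_id = character(), sentence_index = integer(),
    subject_id = character(), predicate = character(),
    object_id = character(), value = double(), unit = character()
  )
}

#' Extract subject-predicate-object triples from an annotated document
#'
#' Assembles entity spans into sentence-local triples with nearest-mention
#' attachment: each quantity + unit pair attaches to the nearest preceding
#' substance span in the sentence (falling back to the nearest following
#' one) as `has_dosage`; each route span attaches to the nearest substance
#' span as `administered_via`; each form span as `has_form`; every pair of
#' distinct substance spans in a sentence yields `co_mentioned_with`.
#' Distance is measured in characters; ties break toward the preceding
#' span. No triple crosses a sentence boundary.
#'
#' @param spans A `dao_annotations` tibble from [annotate()] (must carry its
#'   `text` attribute) or any span tibble plus `text`.
#' @param lexicon The `dao_lexicon` used to produce the spans (supplies
#'   concept kinds and unit labels).
#' @param text The raw document text; defaults to the spans' attribute.
#' @return Tibble with columns `doc_id`, `sentence_index`, `subject_id`,
#'   `predicate`, `object_id`, `value`, `unit`.
#' @examples
#' lex <- compile_lexicon(build_fixture_dao())
#' ann <- annotate("injected 2 mg of bupe", lex)
#' extract_triples(ann, lex)
#' @export
extract_triples <- function(spans, lexicon, text = attr(spans, "text")) {
  if (is.null(text)) abort("extract_triples needs the document text")
  if (!nrow(spans)) return(empty_triples())
  doc <- spans$doc_id[1]
  sents <- split_sentences(text)
  kind <- lexicon_kind_of(lexicon, spans$concept_id)
  mid <- (spans$start + spans$end) / 2
  out <- list()
  emit <- function(si, subj, pred, obj, value = NA_real_,
                   unit = NA_character_) {
    out[[length(out) + 1L]] <<- tibble(
      doc_id = doc, sentence_index = si, subject_id = subj,
      predicate = pred, object_id = obj, value = value, unit = unit
    )
  }
  for (s in seq_len(nrow(sents))) {
    si <- sents$sentence_index[s]
    in_sent <- spans$start >= sents$start[s] & spans$end <= sents$end[s]
    sub_i <- which(in_sent & kind %in% substance_kinds)
    if (!length(sub_i)) next

    nearest_substance <- function(pos, prefer_preceding_only = FALSE) {
      prec <- sub_i[spans$end[sub_i] <= pos]
      foll <- sub_i[spans$start[sub_i] >= pos]
      if (prefer_preceding_only && length(prec)) {
        return(prec[which.max(spans$end[prec])])
      }
      cand <- sub_i
      d <- abs(mid[cand] - pos)
      best <- cand[d == min(d)]
      if (length(best) > 1L) {
        # tie toward the preceding span
        pb <- best[spans$end[best] <= pos]
        best <- if (length(pb)) pb[which.max(spans$end[pb])] else best[1]
      }
      best[1]
    }

    # dosage: unit span with an immediately preceding numeric literal
    unit_i <- which(in_sent & kind == "unit")
    for (u in unit_i) {
      q <- preceding_quantity(text, spans$start[u])
      if (is.null(q)) next
      subj <- {
        prec <- sub_i[spans$end[sub_i] <= q$start]
        if (length(prec)) prec[which.max(spans$end[prec])] else {
          foll <- sub_i[spans$start[sub_i] >= spans$end[u]]
          if (length(foll)) foll[which.min(spans$start[foll])] else NA
        }
      }
      if (is.na(subj)) next
      emit(si, spans$concept_id[subj], "has_dosage",
           spans$canonical_label[u], q$value, spans$canonical_label[u])
    }

    route_i <- which(in_sent & kind == "route")
    for (r in route_i) {
      subj <- nearest_substance(mid[r])
      emit(si, spans$concept_id[subj], "administered_via",
           spans$concept_id[r])
    }

    form_i <- which(in_sent & kind %in% c("form", "preparation"))
    for (f in form_i) {
      subj <- nearest_substance(mid[f])
      emit(si, spans$concept_id[subj], "has_form", spans$concept_id[f])
    }

    if (length(sub_i) > 1L) {
      ord <- sub_i[order(spans$start[sub_i])]
      for (a in seq_len(length(ord) - 1L)) {
        for (b in seq.int(a + 1L, length(ord))) {
          if (spans$concept_id[ord[a]] == spans$concept_id[ord[b]]) next
          emit(si, spans$concept_id[ord[a]], "co_mentioned_with",
               spans$concept_id[ord[b]])
        }
      }
    }
  }
  if (!length(out)) return(empty_triples())
  dplyr::bind_rows(out)
}

#' Write triples to JSONL
#'
#' @param triples Tibble from [extract_triples()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_triples_jsonl <- function(triples, path) {
  lines <- vapply(seq_len(nrow(triples)), function(i) {
    row <- as.list(triples[i, ])
    row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
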