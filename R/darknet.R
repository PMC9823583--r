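#' Built-in mass-unit conversion table
#'
#' Surface forms and gram factors used by [normalize_dosage()]: mcg / ug /
#' \eqn{\mu}g at 1e-6, mg at 1e-3, g / gram at 1, kg at 1e3, oz / ounce at
#' 28.3495, lb at 453.592.
#'
#' @return A unit tibble in the same shape as an ontology's `units` table.
#' @export
mass_units <- function() {
  tibble(
    id = c("Mcg", "Mg", "Gram", "Kg", "Ounce", "Lb"),
    canonical_label = c("MICROGRAM", "MILLIGRAM", "GRAM", "KILOGRAM",
                        "OUNCE", "POUND"),
    dimension = "mass",
    to_grams = c(1e-6, 1e-3, 1, 1e3, 28.3495, 453.592),
    surface_forms = list(
      c("mcg", "ug", "µg", "microgram", "micrograms"),
      c("mg", "milligram", "milligrams"),
      c("g", "gram", "grams"),
      c("kg", "kilogram", "kilograms"),
      c("oz", "ounce", "ounces"),
      c("lb", "lbs", "pound", "pounds")
    )
  )
}

rate_suffix_re <- "(?:\\s*(?:per\\s*h(?:ou)?r?|/\\s*h(?:ou)?r?))\\s*$"

#' Normalize a dosage to grams
#'
#' Converts a value with a mass-unit surface form (optionally carrying a
#' per-hour rate suffix, as in transdermal patch strengths like
#' "100 mcg per h") into grams. The conversion table defaults to
#' [mass_units()]; an ontology's unit table can be passed instead.
#'
#' @param value Numeric dose value.
#' @param unit_surface Unit surface string, e.g. `"mcg per h"`, `"oz"`.
#' @param units Unit table (tibble with `canonical_label`, `dimension`,
#'   `to_grams`, `surface_forms`).
#' @return A list with `grams`, `is_rate` (per-hour flag) and `unit`
#'   (canonical unit label).
#' @examples
#' normalize_dosage(100, "mcg per h")  # 1e-4 g, rate
#' normalize_dosage(2, "oz")           # 56.699 g
#' @export
normalize_dosage <- function(value, unit_surface, units = mass_units()) {
  stopifnot(is.numeric(value), length(unit_surface) == 1L)
  raw <- unit_surface
  is_rate <- grepl(rate_suffix_re, raw, perl = TRUE, ignore.case = TRUE)
  bare <- sub(rate_suffix_re, "", raw, perl = TRUE, ignore.case = TRUE)
  bare <- normalize_surface(bare)
  hit <- NA_integer_
  for (i in seq_len(nrow(units))) {
    if (bare %in% normalize_surface(units$surface_forms[[i]])) {
      hit <- i
      break
    }
  }
  if (is.na(hit)) {
    abort(paste0("unknown unit: ", unit_surface), class = "dao_unknown_unit")
  }
  if (units$dimension[hit] != "mass") {
    abort(paste0("not a mass unit: ", unit_surface),
          class = "dao_dimension_error")
  }
  list(
    grams = value * units$to_grams[hit],
    is_rate = is_rate,
    unit = units$canonical_label[hit]
  )
}

first_span <- function(spans, sel) {
  i <- which(sel)
  if (!length(i)) return(NULL)
  i[which.min(spans$start[i])]
}

# quantity + mass-unit match inside free text; returns first occurrence
first_dosage <- function(text, units) {
  surfs <- unlist(lapply(seq_len(nrow(units)), function(i) {
    if (units$dimension[i] == "mass") units$surface_forms[[i]] else character()
  }))
  if (!length(surfs)) return(NULL)
  surfs <- surfs[order(-nchar(surfs))]
  alt <- paste(gsub("([][.\\^$|()*+?{}-])", "\\\\\\1", surfs, perl = TRUE),
               collapse = "|")
  re <- paste0(
    "(?<![A-Za-z0-9])([0-9]+(?:\\.[0-9]+)?)\\s*(", alt,
    ")(?![A-Za-z])((?:\\s*(?:per\\s*h(?:ou)?r?|/\\s*h(?:ou)?r?))?)"
  )
  m <- regexpr(re, text, perl = TRUE, ignore.case = TRUE)
  if (m[1] == -1L) return(NULL)
  st <- attr(m, "capture.start")
  le <- attr(m, "capture.length")
  value <- as.numeric(substring(text, st[1], st[1] + le[1] - 1L))
  unit_surface <- substring(text, st[2], st[2] + le[2] - 1L)
  rate <- le[3] > 0L
  d <- normalize_dosage(value, unit_surface, units)
  list(grams = d$grams, is_rate = rate || d$is_rate, unit = d$unit,
       value = value)
}

#' Parse one cryptomarket listing into structured fields
#'
#' Dictionary NER over a listing title and description: the substance is
#' the longest-matching substance concept in the title (falling back to the
#' description), its reporting class is the substance-type ancestor (so a
#' fentanyl analog resolves to "fentanyl-type"); the dosage is the first
#' quantity + mass-unit match, normalized to grams with a per-hour rate
#' flag; the form is the first dosage-form match. Cryptomarket
#' abbreviations in the lexicon are matched like any other surface (fuff
#' resolves to fluoro-furanyl fentanyl); the case-sensitive transaction
#' term FE ("finalize early") sets a flag and is never read as a substance
#' or form. Listings with no substance match are returned flagged
#' `unresolved`, not dropped.
#'
#' @param title,description Listing text fields (description may be `""`).
#' @param lexicon A `dao_lexicon` compiled from an ontology with opioid
#'   subclasses, forms and units.
#' @param ontology The source `dao_ontology` (for class ancestry).
#' @param units Mass-unit table; defaults to [mass_units()].
#' @return A one-row tibble with `substance_id`, `substance_name`,
#'   `substance_class`, `dosage_value_g`, `dosage_is_rate`, `dosage_unit`,
#'   `form`, `finalize_early`, `unresolved`.
#' @examples
#' onto <- build_fixture_dao()
#' lex <- compile_lexicon(onto)
#' parse_listing("FENTANYL TRANSDERMAL PATCHES 100 mcg per h", "", lex, onto)
#' @export
parse_listing <- function(title, description = "", lexicon, ontology,
                          units = mass_units()) {
  if (is.null(description) || is.na(description)) description <- ""
  if (is.na(title)) title <- ""
  find_sub <- function(txt) {
    if (is.na(txt) || !nzchar(txt)) return(NULL)
    sp <- annotate(txt, lexicon)
    k <- lexicon_kind_of(lexicon, sp$concept_id)
    sub <- sp[k %in% substance_kinds, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    # longest surface match wins; ties to the leftmost
    len <- sub$end - sub$start
    sub[order(-len, sub$start), , drop = FALSE][1, ]
  }
  spans_title <- annotate(title, lexicon)
  best <- find_sub(title)
  if (is.null(best)) best <- find_sub(description)

  d <- first_dosage(title, units)
  if (is.null(d) && nzchar(description %||% "")) {
    d <- first_dosage(description, units)
  }

  k_title <- lexicon_kind_of(lexicon, spans_title$concept_id)
  form_i <- first_span(spans_title, k_title == "form")
  form <- if (!is.null(form_i)) spans_title$canonical_label[form_i] else {
    sp2 <- if (nzchar(description %||% "")) annotate(description, lexicon)
           else empty_spans()
    k2 <- lexicon_kind_of(lexicon, sp2$concept_id)
    j <- first_span(sp2, k2 == "form")
    if (!is.null(j)) sp2$canonical_label[j] else NA_character_
  }

  fe <- any(spans_title$concept_id == "Finalize_Early") ||
    (nzchar(description %||% "") &&
       any(annotate(description, lexicon)$concept_id == "Finalize_Early"))

  tibble(
    substance_id = if (is.null(best)) NA_character_ else best$concept_id,
    substance_name = if (is.null(best)) NA_character_ else
      best$canonical_label,
    substance_class = if (is.null(best)) NA_character_ else
      substance_class_of(ontology, best$concept_id),
    dosage_value_g = if (is.null(d)) NA_real_ else d$grams,
    dosage_is_rate = if (is.null(d)) NA else d$is_rate,
    dosage_unit = if (is.null(d)) NA_character_ else d$unit,
    form = form,
    finalize_early = fe,
    unresolved = is.null(best)
  )
}

#' Parse a table of cryptomarket listings
#'
#' Vectorized [parse_listing()] over a listings table, carrying through the
#' metadata columns and adding a digest of the description for distinctness
#' summaries.
#'
#' @param listings Data frame with columns `listing_id`, `market`,
#'   `crawl_date` (Date or ISO-8601 string), `vendor_id`, `title`,
#'   `description`, `location`.
#' @inheritParams parse_listing
#' @return A tibble of listing records: the metadata columns plus the
#'   parsed fields of [parse_listing()] and `description_digest`.
#' @export
parse_listings <- function(listings, lexicon, ontology,
                           units = mass_units()) {
  listings <- as_tibble(listings)
  if (!nrow(listings)) {
    return(dplyr::bind_cols(
      listings,
      tibble(substance_id = character(), substance_name = character(),
             substance_class = character(), dosage_value_g = double(),
             dosage_is_rate = logical(), dosage_unit = character(),
             form = character(), finalize_early = logical(),
             unresolved = logical(),
             description_digest = character())[0, ]
    ))
  }
  parsed <- purrr::map2(
    listings$title, listings$description %||% rep("", nrow(listings)),
    function(t, d) parse_listing(t, d %||% "", lexicon, ontology, units)
  )
  out <- dplyr::bind_cols(listings, dplyr::bind_rows(parsed))
  out$crawl_date <- as.Date(out$crawl_date)
  out$description_digest <- vapply(
    out$description %||% rep("", nrow(out)),
    function(d) rlang::hash(d %||% ""), character(1), USE.NAMES = FALSE
  )
  out
}

#' Substance-type row label for availability reporting
#'
#' Maps each parsed record to its reporting row: "fentanyl" (including
#' pharmaceutical/brand mentions), the individual fentanyl analogs, the
#' individual nonpharmaceutical synthetic opioids, or "other opioids"
#' (heroin, morphine, and pharmaceutical opioids excluding pharmaceutical
#' fentanyl).
#'
#' @param records Parsed listing records from [parse_listings()].
#' @param ontology The source ontology.
#' @return Character vector of row labels (`NA` for unresolved records).
#' @export
substance_type_of <- function(records, ontology) {
  co <- ontology$concepts
  vapply(seq_len(nrow(records)), function(i) {
    id <- records$substance_id[i]
    if (is.na(id)) return(NA_character_)
    cls <- records$substance_class[i]
    if (identical(id, "Fentanyl")) return("fentanyl")
    if (identical(cls, "fentanyl-type")) {
      return(co$label[match(id, co$id)]) # each analog is its own row
    }
    if (identical(cls, "other NP synthetic opioids")) {
      return(co$label[match(id, co$id)])
    }
    anc <- c(id, concept_ancestors(ontology, id))
    if ("Opioid" %in% anc) return("other opioids")
    cls
  }, character(1))
}

#' Average advertisements per day by market, month and substance type
#'
#' For each market and calendar month, the mean over distinct crawl dates
#' of the number of listings per date, split by substance-type row (see
#' [substance_type_of()]). Dates with no crawl are excluded from the
#' denominator, so averages are per crawl-day; a substance type absent on a
#' crawl date contributes a zero for that date. Unresolved records are
#' ignored.
#'
#' @param records Parsed listing records carrying `market`, `crawl_date`.
#' @param ontology The source ontology.
#' @return Tibble with columns `market`, `month` (`"YYYY-MM"`),
#'   `substance_type`, `n_crawls`, `mean_per_day`. Every reporting row
#'   (see [substance_type_rows()]) appears for every market-month with a
#'   crawl, with zero means for substance types not advertised.
#' @export
aggregate_daily_averages <- function(records, ontology) {
  if (!nrow(records)) {
    return(tibble(market = character(), month = character(),
                  substance_type = character(), n_crawls = integer(),
                  mean_per_day = double()))
  }
  rec <- as_tibble(records)
  rec$substance_type <- substance_type_of(rec, ontology)
  rec$month <- format(as.Date(rec$crawl_date), "%Y-%m")
  crawls <- dplyr::summarise(
    dplyr::group_by(rec, .data$market, .data$month),
    n_crawls = dplyr::n_distinct(.data$crawl_date), .groups = "drop"
  )
  rec <- rec[!is.na(rec$substance_type), , drop = FALSE]
  counts <- dplyr::count(rec, .data$market, .data$month, .data$substance_type,
                         name = "n_listings")
  grid <- tidyr::expand_grid(
    dplyr::distinct(crawls[, c("market", "month")]),
    substance_type = union(substance_type_rows(ontology),
                           unique(counts$substance_type))
  )
  out <- dplyr::left_join(grid, counts,
                          by = c("market", "month", "substance_type"))
  out$n_listings[is.na(out$n_listings)] <- 0L
  out <- dplyr::left_join(out, crawls, by = c("market", "month"))
  out$mean_per_day <- out$n_listings / out$n_crawls
  dplyr::select(out, "market", "month", "substance_type", "n_crawls",
                mean_per_day = "mean_per_day")
}

#' Standard substance-type reporting rows for an ontology
#'
#' The availability table rows: "fentanyl", one row per fentanyl analog,
#' one per nonpharmaceutical synthetic opioid, and "other opioids".
#'
#' @param ontology A `dao_ontology`.
#' @return Character vector of row labels.
#' @export
substance_type_rows <- function(ontology) {
  co <- ontology$concepts
  analogs <- co$label[!is.na(co$parent_id) & co$parent_id == "Fentanyl_Type" &
                        co$id != "Fentanyl"]
  np <- co$label[!is.na(co$parent_id) &
                   co$parent_id == "Other_NP_Synthetic_Opioid"]
  c("fentanyl", analogs, np, "other opioids")
}

#' Per-marketplace summary of distinct vendors, substances and locations
#'
#' @param records Parsed listing records.
#' @return Tibble with one row per market: `n_transactions` (records),
#'   `n_vendors`, `n_substances`, `n_locations`, `n_descriptions`
#'   (all distinct counts).
#' @export
summarize_marketplace <- function(records) {
  if (!nrow(records)) {
    return(tibble(market = character(), n_transactions = integer(),
                  n_vendors = integer(), n_substances = integer(),
                  n_locations = integer(), n_descriptions = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(records), .data$market),
    n_transactions = dplyr::n(),
    n_vendors = dplyr::n_distinct(.data$vendor_id),
    n_substances = dplyr::n_distinct(.data$substance_name[
      !is.na(.data$substance_name)]),
    n_locations = dplyr::n_distinct(.data$location),
    n_descriptions = dplyr::n_distinct(.data$description_digest),
    .groups = "drop"
  )
}

#' Plot average advertisements per day
#'
#' @param agg Output of [aggregate_daily_averages()].
#' @param types Optional subset of substance types to show.
#' @return A ggplot object.
#' @export
plot_daily_averages <- function(agg, types = NULL) {
  if (!is.null(types)) {
    agg <- agg[agg$substance_type %in% types, , drop = FALSE]
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$month, y = .data$mean_per_day,
                                    fill = .data$substance_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$market), scales = "free_x") +
    ggplot2::labs(x = "month", y = "mean advertisements per crawl-day",
                  fill = "substance type") +
    ggplot2::theme_minimal()
}
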