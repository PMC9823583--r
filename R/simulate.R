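#' Generator parameters for synthetic corpora
#'
#' @param n_docs Number of forum posts to generate.
#' @param p_slang Probability a drug mention is rendered as a slang, street
#'   or brand form instead of the canonical name.
#' @param p_unit Probability a post carries a quantity + unit phrase.
#' @param p_route Probability a post carries a route-of-administration word.
#' @param noise_rate Per-character probability of a letter substitution,
#'   applied only outside gold spans so gold offsets stay valid.
#' @param distractor_rate Probability a post carries a drug-like nonsense
#'   word that is not in the ontology.
#' @param n_days,lambda Listing generation: days of crawling and the
#'   Poisson mean number of listings per market per day.
#' @param p_rate_pattern Probability a listing uses the transdermal
#'   patch-strength pattern ("NAME TRANSDERMAL PATCHES v mcg per h").
#' @param markets,n_vendors,start_date Listing metadata configuration.
#' @param seed Integer seed; identical parameters and seed reproduce an
#'   identical corpus.
#' @return A list of class `dao_sim_params`.
#' @export
sim_params <- function(n_docs = 100L, p_slang = 0.4, p_unit = 0.7,
                       p_route = 0.6, noise_rate = 0, distractor_rate = 0,
                       n_days = 30L, lambda = 7, p_rate_pattern = 0.3,
                       markets = "Agora", n_vendors = 5L,
                       start_date = "2015-03-01", seed = 1L) {
  p <- list(
    n_docs = as.integer(n_docs), p_slang = p_slang, p_unit = p_unit,
    p_route = p_route, noise_rate = noise_rate,
    distractor_rate = distractor_rate, n_days = as.integer(n_days),
    lambda = lambda, p_rate_pattern = p_rate_pattern, markets = markets,
    n_vendors = as.integer(n_vendors), start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  probs <- c(p$p_slang, p$p_unit, p$p_route, p$noise_rate,
             p$distractor_rate, p$p_rate_pattern)
  stopifnot(all(probs >= 0 & probs <= 1), p$lambda > 0)
  structure(p, class = "dao_sim_params")
}

with_corpus_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

forum_fillers <- c("honestly", "yesterday", "felt", "fine", "then", "slept",
                   "all", "day", "really", "rough", "week")
distractor_words <- c("zorbinol", "quexadrine", "velatrax", "numbryl")

#' Generate a seeded forum-style gold corpus
#'
#' Builds template posts of the shape
#' `"i <route> <qty> <unit> of <drug-surface> <fillers>."` from a validated
#' ontology. The drug surface is a slang/street/brand attachment with
#' probability `p_slang` (the gold concept is always the canonical
#' concept), the quantity + unit phrase appears with probability `p_unit`
#' and the route word with probability `p_route`. Gold spans are recorded
#' at exact 0-based character offsets for the drug, unit and route
#' mentions; character-substitution noise is applied only outside gold
#' spans, and distractor pseudo-drug words are never annotated.
#'
#' @param ontology A `dao_ontology` with at least one substance (and one
#'   slang-bearing substance when `p_slang > 0`).
#' @param params A [sim_params()] list.
#' @return A list of class `dao_gold_corpus`: `documents` (doc_id, text),
#'   `gold_spans` (standoff spans), `gold_tuples` (the sampled
#'   drug/dose/route ground truth) and `params`.
#' @export
generate_forum_corpus <- function(ontology, params = sim_params()) {
  co <- ontology$concepts
  te <- ontology$terms
  subs <- co$id[co$kind %in% substance_kinds]
  if (!length(subs)) abort("ontology has no substance concepts")
  slangy <- c("slang", "street", "brand")
  slang_subs <- unique(te$concept_id[te$concept_id %in% subs &
                                       te$term_type %in% slangy])
  if (params$p_slang > 0 && !length(slang_subs)) {
    abort("p_slang > 0 but the ontology has no slang-bearing substance",
          class = "dao_parameter_error")
  }
  routes <- co$id[co$kind == "route"]
  route_surf <- te[te$concept_id %in% routes, , drop = FALSE]
  mass <- ontology$units[ontology$units$dimension == "mass", , drop = FALSE]

  with_corpus_seed(params$seed, {
    docs <- vector("list", params$n_docs)
    spans <- vector("list", params$n_docs)
    tuples <- vector("list", params$n_docs)
    for (d in seq_len(params$n_docs)) {
      doc_id <- sprintf("post%04d", d)
      text <- ""
      gold <- list()
      put <- function(s) text <<- paste0(text, s)
      put_gold <- function(s, concept_id, canonical_label, term_type,
                           category) {
        start <- nchar(text)
        put(s)
        gold[[length(gold) + 1L]] <<- tibble(
          doc_id = doc_id, start = start, end = nchar(text), surface = s,
          concept_id = concept_id, canonical_label = canonical_label,
          term_type = term_type, category = category
        )
      }

      use_slang <- stats::runif(1) < params$p_slang
      drug <- if (use_slang) sample1(slang_subs) else sample1(subs)
      drug_label <- co$label[match(drug, co$id)]
      if (use_slang) {
        opts <- te[te$concept_id == drug & te$term_type %in% slangy, ,
                   drop = FALSE]
        k <- sample1(seq_len(nrow(opts)))
        drug_surface <- opts$surface[k]
        drug_type <- opts$term_type[k]
      } else {
        drug_surface <- drug_label
        drug_type <- "canonical"
      }

      route_id <- NA_character_
      value <- NA_real_
      unit_id <- NA_character_

      put("i ")
      if (nrow(route_surf) && stats::runif(1) < params$p_route) {
        k <- sample1(seq_len(nrow(route_surf)))
        route_id <- route_surf$concept_id[k]
        put_gold(route_surf$surface[k], route_id,
                 co$label[match(route_id, co$id)], route_surf$term_type[k],
                 "route")
        put(" ")
      } else {
        put("took ")
      }
      if (nrow(mass) && stats::runif(1) < params$p_unit) {
        value <- sample1(c(1, 2, 4, 8, 10))
        k <- sample1(seq_len(nrow(mass)))
        unit_id <- mass$id[k]
        put(paste0(value, " "))
        put_gold(sample1(mass$surface_forms[[k]]), unit_id,
                 mass$canonical_label[k], "canonical", "unit")
        put(" of ")
      }
      put_gold(drug_surface, drug, drug_label, drug_type,
               substance_class_of(ontology, drug))
      if (stats::runif(1) < params$distractor_rate) {
        put(paste0(" with ", sample1(distractor_words)))
      }
      n_fill <- sample1(1:3)
      put(paste0(" ", paste(sample(forum_fillers, n_fill), collapse = " ")))
      put(".")

      gold_df <- dplyr::bind_rows(gold)
      if (params$noise_rate > 0) {
        text <- add_noise(text, gold_df, params$noise_rate)
      }
      docs[[d]] <- tibble(doc_id = doc_id, text = text)
      spans[[d]] <- gold_df
      tuples[[d]] <- tibble(
        doc_id = doc_id, drug_id = drug, value = value, unit_id = unit_id,
        route_id = route_id
      )
    }
    structure(
      list(
        documents = dplyr::bind_rows(docs),
        gold_spans = dplyr::bind_rows(spans),
        gold_tuples = dplyr::bind_rows(tuples),
        params = params
      ),
      class = "dao_gold_corpus"
    )
  })
}

# letter substitutions outside protected [start,end) windows
add_noise <- function(text, gold_spans, rate) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  protected <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(gold_spans))) {
    protected[(gold_spans$start[i] + 1L):gold_spans$end[i]] <- TRUE
  }
  hit <- which(!protected & grepl("[a-z]", chars) & stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- sample(letters, length(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' @export
print.dao_gold_corpus <- function(x, ...) {
  what <- if (!is.null(x$documents)) {
    paste0(nrow(x$documents), " documents, ", nrow(x$gold_spans),
           " gold spans")
  } else {
    paste0(nrow(x$listings), " listings")
  }
  cat("<dao_gold_corpus> ", what, " (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

listing_locations <- c("US", "DE", "NL", "CA", "AU")

#' Generate a seeded cryptomarket listing gold corpus
#'
#' For each market and each of `n_days` consecutive crawl dates, draws a
#' Poisson(`lambda`) number of listings. Each listing samples a substance
#' from the ontology's opioid subclasses, a dose and mass unit, a form and
#' a vendor, and renders a title either as
#' `"<NAME> <FORM> <value> <unit>"` or, with probability `p_rate_pattern`,
#' as the patch-strength pattern `"<NAME> TRANSDERMAL PATCHES <value> mcg
#' per h"`. The sampled ground truth (concept, dosage in grams, rate flag,
#' form) is stored alongside each listing.
#'
#' @inheritParams generate_forum_corpus
#' @return A list of class `dao_gold_corpus` with a `listings` tibble
#'   (metadata + title + gold fields prefixed `gold_`) and `params`.
#' @export
generate_listing_corpus <- function(ontology, params = sim_params()) {
  co <- ontology$concepts
  is_sub <- co$kind %in% substance_kinds
  leaves <- co$id[is_sub & !(co$id %in% co$parent_id[!is.na(co$parent_id)])]
  opioids <- leaves[vapply(leaves, function(id) {
    "Opioid" %in% c(id, concept_ancestors(ontology, id))
  }, logical(1))]
  if (!length(opioids)) abort("ontology has no opioid substances")
  mass <- ontology$units[ontology$units$dimension == "mass", , drop = FALSE]
  if (!nrow(mass)) abort("ontology has no mass units")
  forms <- co[co$kind == "form", , drop = FALSE]

  with_corpus_seed(params$seed, {
    rows <- list()
    n_id <- 0L
    for (mkt in params$markets) {
      for (day in seq_len(params$n_days) - 1L) {
        date <- params$start_date + day
        n <- stats::rpois(1, params$lambda)
        for (k in seq_len(n)) {
          n_id <- n_id + 1L
          drug <- sample1(opioids)
          drug_label <- co$label[match(drug, co$id)]
          vendor <- sprintf("v%03d", sample1(seq_len(params$n_vendors)))
          rate <- stats::runif(1) < params$p_rate_pattern
          if (rate) {
            value <- sample1(c(25, 50, 75, 100))
            title <- paste0(toupper(drug_label), " TRANSDERMAL PATCHES ",
                            value, " mcg per h")
            grams <- value * 1e-6
            form <- "transdermal"
          } else {
            value <- sample1(c(0.5, 1, 2, 5, 10))
            u <- sample1(which(mass$canonical_label != "MICROGRAM"))
            surf <- sample1(mass$surface_forms[[u]])
            form_row <- sample1(seq_len(nrow(forms)))
            form <- forms$label[form_row]
            title <- paste0(toupper(drug_label), " ", toupper(form), " ",
                            value, " ", surf)
            grams <- value * mass$to_grams[u]
          }
          rows[[length(rows) + 1L]] <- tibble(
            listing_id = sprintf("L%05d", n_id),
            market = mkt,
            crawl_date = date,
            vendor_id = vendor,
            title = title,
            description = "",
            location = sample1(listing_locations),
            gold_substance_id = drug,
            gold_substance_class = substance_class_of(ontology, drug),
            gold_dosage_value_g = grams,
            gold_dosage_is_rate = rate,
            gold_form = form
          )
        }
      }
    }
    structure(
      list(listings = dplyr::bind_rows(rows), params = params),
      class = "dao_gold_corpus"
    )
  })
}

#' Write a gold corpus to disk
#'
#' Documents/listings and gold annotations are written as JSONL/CSV; the
#' generator parameters are echoed into a sidecar JSON file.
#'
#' @param corpus A `dao_gold_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gold_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(corpus$documents)) {
    write_standoff_jsonl(corpus$documents, corpus$gold_spans,
                         file.path(dir, "gold.jsonl"))
  }
  if (!is.null(corpus$listings)) {
    utils::write.csv(corpus$listings, file.path(dir, "listings.csv"),
                     row.names = FALSE)
  }
  p <- unclass(corpus$params)
  p$start_date <- as.character(p$start_date)
  writeLines(
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA)),
    file.path(dir, "params.json")
  )
  invisible(dir)
}
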