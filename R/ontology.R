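#' @importFrom rlang .data abort hash
#' @importFrom tibble tibble as_tibble
NULL

concept_kinds <- c(
  "substance_class", "substance_instance", "unit", "form", "route",
  "preparation", "dsm5_category", "mental_health_term"
)

term_types <- c(
  "canonical", "brand", "street", "slang", "synonym", "abbreviation",
  "chemical_formula", "lay_term"
)

unit_dimensions <- c("mass", "volume", "count", "mass_rate")

# Which parent kinds are legal for a child of each kind.
parent_kind_compat <- list(
  substance_class    = "substance_class",
  substance_instance = c("substance_class", "substance_instance"),
  unit               = "unit",
  form               = "form",
  route              = "route",
  preparation        = "preparation",
  dsm5_category      = "dsm5_category",
  mental_health_term = c("dsm5_category", "mental_health_term")
)

empty_concepts <- function() {
  tibble(
    id = character(), label = character(), kind = character(),
    parent_id = character()
  )
}

empty_terms <- function() {
  tibble(
    concept_id = character(), surface = character(), term_type = character(),
    case_sensitive = logical()
  )
}

empty_units <- function() {
  tibble(
    id = character(), canonical_label = character(), dimension = character(),
    to_grams = double(), surface_forms = list()
  )
}

empty_annotations <- function() {
  tibble(subject_id = character(), property = character(), value = character())
}

#' Construct an in-memory ontology
#'
#' An ontology is a bundle of tidy tables: a concept hierarchy (psychoactive
#' substance classes and instances, dosage forms, routes of administration,
#' preparation practices, DSM-5 diagnostic categories and mental-health
#' terms), surface-term attachments (brand, street, slang, synonym,
#' abbreviation, chemical-formula and lay terms), measurement units with
#' their surface forms and gram-conversion factors, declared property names,
#' and free annotation triples.
#'
#' The constructor validates the bundle with [validate_ontology()] and
#' refuses to build an object with error-grade violations (dangling
#' references, parent cycles, empty labels, malformed units).
#'
#' @param concepts Data frame with columns `id`, `label`, `kind`
#'   (one of `r paste0('\x60', concept_kinds, '\x60', collapse = ", ")`) and
#'   optional `parent_id`.
#' @param terms Data frame with columns `concept_id`, `surface`, `term_type`,
#'   and optional logical `case_sensitive`.
#' @param units Data frame with columns `id`, `canonical_label`, `dimension`,
#'   `to_grams` (mass units only) and a list-column `surface_forms`.
#' @param object_properties,data_properties Character vectors of declared
#'   property names.
#' @param annotations Data frame with columns `subject_id`, `property`,
#'   `value` (literal).
#' @return An object of class `dao_ontology`.
#' @examples
#' onto <- dao_ontology(
#'   concepts = tibble::tibble(
#'     id = c("Opioid", "Morphine"), label = c("opioid", "morphine"),
#'     kind = "substance_class", parent_id = c(NA, "Opioid")
#'   )
#' )
#' onto
#' @export
dao_ontology <- function(concepts = empty_concepts(),
                         terms = empty_terms(),
                         units = empty_units(),
                         object_properties = character(),
                         data_properties = character(),
                         annotations = empty_annotations()) {
  concepts <- as_tibble(concepts)
  if (!"parent_id" %in% names(concepts)) concepts$parent_id <- NA_character_
  concepts$parent_id <- as.character(concepts$parent_id)
  concepts$parent_id[!is.na(concepts$parent_id) &
                       concepts$parent_id == ""] <- NA_character_
  terms <- as_tibble(terms)
  if (nrow(terms) && !"case_sensitive" %in% names(terms)) {
    terms$case_sensitive <- FALSE
  }
  if (!nrow(terms)) terms <- empty_terms()
  terms$case_sensitive <- as.logical(terms$case_sensitive)
  units <- as_tibble(units)
  if (!nrow(units)) units <- empty_units()
  if (!is.list(units$surface_forms)) {
    units$surface_forms <- as.list(units$surface_forms)
  }
  onto <- structure(
    list(
      concepts = concepts, terms = terms, units = units,
      object_properties = sort(unique(object_properties)),
      data_properties = sort(unique(data_properties)),
      annotations = as_tibble(annotations)
    ),
    class = "dao_ontology"
  )
  bad <- validate_ontology(onto)
  bad <- bad[bad$severity == "error", , drop = FALSE]
  if (nrow(bad)) {
    abort(paste0(
      "invalid ontology:\n",
      paste0("- ", bad$rule, ": ", bad$detail, collapse = "\n")
    ), class = "dao_integrity_error")
  }
  onto
}

#' @export
print.dao_ontology <- function(x, ...) {
  cat(
    "<dao_ontology> ", nrow(x$concepts), " concepts, ",
    nrow(x$terms), " term attachments, ", nrow(x$units), " units, ",
    length(x$object_properties), " object properties, ",
    length(x$data_properties), " data properties\n",
    sep = ""
  )
  kinds <- table(x$concepts$kind)
  if (length(kinds)) {
    cat("  ", paste0(names(kinds), ": ", as.integer(kinds), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

violation <- function(rule, severity, detail) {
  tibble(rule = rule, severity = severity, detail = detail)
}

#' Validate an ontology's structural invariants
#'
#' Checks referential integrity (every term and annotation subject resolves,
#' every parent exists), acyclicity of the parent graph, kind compatibility
#' of parent links, non-empty labels, uniqueness of concept ids and of
#' (concept, surface, term type) attachments, unit well-formedness (mass
#' units carry a positive gram factor, non-mass units carry none, surface
#' forms disjoint across units), and flags -- as warning-grade records --
#' identical surfaces attached to different concepts under the same parent.
#'
#' Violations are data, not exceptions: the return value is a tibble with
#' one row per violation (`rule`, `severity`, `detail`), empty when the
#' ontology is clean.
#'
#' @param ontology A `dao_ontology` or a compatible list of tables.
#' @return A tibble of violation records.
#' @export
validate_ontology <- function(ontology) {
  co <- ontology$concepts
  te <- ontology$terms
  un <- ontology$units
  an <- ontology$annotations
  out <- list()

  dup_id <- co$id[duplicated(co$id)]
  if (length(dup_id)) {
    out <- c(out, list(violation(
      "duplicate_concept_id", "error", paste(unique(dup_id), collapse = ", ")
    )))
  }
  bad_kind <- setdiff(unique(co$kind), concept_kinds)
  if (length(bad_kind)) {
    out <- c(out, list(violation(
      "unknown_kind", "error", paste(bad_kind, collapse = ", ")
    )))
  }
  empty_lab <- co$id[is.na(co$label) | !nzchar(trimws(co$label))]
  if (length(empty_lab)) {
    out <- c(out, list(violation(
      "empty_label", "error", paste(empty_lab, collapse = ", ")
    )))
  }

  has_parent <- !is.na(co$parent_id)
  dangling_parent <- co$id[has_parent & !(co$parent_id %in% co$id)]
  if (length(dangling_parent)) {
    out <- c(out, list(violation(
      "dangling_parent", "error", paste(dangling_parent, collapse = ", ")
    )))
  }

  # cycle check: follow parent pointers from every node
  parent_of <- stats::setNames(co$parent_id, co$id)
  for (id in co$id[has_parent & (co$parent_id %in% co$id)]) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && cur %in% names(parent_of)) {
      if (cur %in% seen) {
        out <- c(out, list(violation("parent_cycle", "error", id)))
        break
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }

  # parent kind compatibility
  ok_parent <- co[has_parent & co$parent_id %in% co$id, , drop = FALSE]
  if (nrow(ok_parent)) {
    pk <- co$kind[match(ok_parent$parent_id, co$id)]
    bad <- mapply(function(kind, pkind) {
      !pkind %in% (parent_kind_compat[[kind]] %||% character())
    }, ok_parent$kind, pk)
    if (any(bad)) {
      out <- c(out, list(violation(
        "incompatible_parent_kind", "error",
        paste(ok_parent$id[bad], collapse = ", ")
      )))
    }
  }

  if (nrow(te)) {
    dangling <- unique(te$concept_id[!(te$concept_id %in% co$id)])
    if (length(dangling)) {
      out <- c(out, list(violation(
        "dangling_term_concept", "error", paste(dangling, collapse = ", ")
      )))
    }
    bad_type <- setdiff(unique(te$term_type), term_types)
    if (length(bad_type)) {
      out <- c(out, list(violation(
        "unknown_term_type", "error", paste(bad_type, collapse = ", ")
      )))
    }
    norm <- normalize_surface(te$surface)
    if (any(!nzchar(norm))) {
      out <- c(out, list(violation(
        "empty_term_surface", "error",
        paste(unique(te$concept_id[!nzchar(norm)]), collapse = ", ")
      )))
    }
    key <- paste(te$concept_id, norm, te$term_type, sep = "\r")
    if (anyDuplicated(key)) {
      out <- c(out, list(violation(
        "duplicate_term_attachment", "error",
        paste(unique(te$surface[duplicated(key)]), collapse = ", ")
      )))
    }
    # same surface attached to two concepts sharing a parent
    att <- tibble(
      concept_id = te$concept_id, norm = norm,
      parent = co$parent_id[match(te$concept_id, co$id)]
    )
    att <- att[!is.na(att$parent), , drop = FALSE]
    if (nrow(att)) {
      grp <- stats::aggregate(
        concept_id ~ norm + parent, data = att,
        FUN = function(x) length(unique(x))
      )
      shared <- grp[grp$concept_id > 1, , drop = FALSE]
      if (nrow(shared)) {
        out <- c(out, list(violation(
          "duplicate_sibling_surface", "warning",
          paste(shared$norm, collapse = ", ")
        )))
      }
    }
  }

  if (nrow(un)) {
    if (anyDuplicated(un$id)) {
      out <- c(out, list(violation("duplicate_unit_id", "error",
                                   paste(un$id[duplicated(un$id)],
                                         collapse = ", "))))
    }
    is_mass <- un$dimension %in% c("mass", "mass_rate")
    bad_mass <- un$id[is_mass & (is.na(un$to_grams) | un$to_grams <= 0)]
    if (length(bad_mass)) {
      out <- c(out, list(violation(
        "mass_unit_without_gram_factor", "error",
        paste(bad_mass, collapse = ", ")
      )))
    }
    bad_nonmass <- un$id[!is_mass & !is.na(un$to_grams)]
    if (length(bad_nonmass)) {
      out <- c(out, list(violation(
        "non_mass_unit_with_gram_factor", "error",
        paste(bad_nonmass, collapse = ", ")
      )))
    }
    surf <- normalize_surface(unlist(un$surface_forms, use.names = FALSE))
    if (anyDuplicated(surf)) {
      out <- c(out, list(violation(
        "unit_surface_collision", "error",
        paste(unique(surf[duplicated(surf)]), collapse = ", ")
      )))
    }
  }

  if (nrow(an)) {
    dangling <- unique(an$subject_id[!(an$subject_id %in% c(co$id, un$id))])
    if (length(dangling)) {
      out <- c(out, list(violation(
        "dangling_annotation_subject", "error",
        paste(dangling, collapse = ", ")
      )))
    }
  }

  if (!length(out)) {
    return(tibble(rule = character(), severity = character(),
                  detail = character()))
  }
  dplyr::bind_rows(out)
}

#' Build the packaged mini-DAO fixture ontology
#'
#' Constructs, from term tables shipped with the package, a small drug-abuse
#' ontology covering the opioid class (buprenorphine with its Suboxone and
#' Subutex brand names and Bupe/Bupey slang; fentanyl with its analogs such
#' as carfentanil and furanyl fentanyl; nonpharmaceutical synthetic opioids
#' such as U-47,700; heroin, morphine with the Poppy Tea home preparation
#' instance, loperamide, methadone and common pharmaceutical opioids), a
#' cannabinoid class with a synthetic-cannabinoid subtype, dosage units
#' (mg, mcg, gram, ounce, ml, caps, bottle), dosage forms and preparation
#' practices (tablet, powder, transdermal, crush, eyeball), routes of
#' administration, the 20 DSM-5 diagnostic categories, and mental-health
#' terms with lay-language attachments (antsy, worried, agitated; "addicted
#' to cannabis"). Cryptomarket abbreviations (fuff for fluoro-furanyl
#' fentanyl; the case-sensitive transaction term FE, "finalize early") are
#' included so listing text can be parsed.
#'
#' The builder is deterministic: repeated calls return equal ontologies.
#'
#' @return A validated `dao_ontology`.
#' @examples
#' onto <- build_fixture_dao()
#' dplyr::filter(onto$terms, concept_id == "Buprenorphine")
#' @export
build_fixture_dao <- function() {
  path <- function(f) system.file("extdata", f, package = "daokit",
                                  mustWork = TRUE)
  co <- utils::read.delim(path("dao_concepts.tsv"), sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  te <- utils::read.delim(path("dao_terms.tsv"), sep = "\t",
                          colClasses = "character")
  te$case_sensitive <- te$case_sensitive == "1"
  un <- utils::read.delim(path("dao_units.tsv"), sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  un <- tibble(
    id = un$id, canonical_label = un$canonical_label,
    dimension = un$dimension, to_grams = as.numeric(un$to_grams),
    surface_forms = strsplit(un$surface_forms, "|", fixed = TRUE)
  )
  dao_ontology(
    concepts = co,
    terms = te,
    units = un,
    object_properties = c(
      "administered_via", "has_dosage", "has_form", "has_interval",
      "co_mentioned_with"
    ),
    data_properties = c(
      "has_brand_name", "has_street_name", "has_slang_term", "has_synonym",
      "has_chemical_formula", "has_abbreviation", "has_lay_term",
      "has_surface_form"
    ),
    annotations = tibble(
      subject_id = c("Finalize_Early", "Poppy_Tea"),
      property = c("comment", "comment"),
      value = c(
        "cryptomarket transaction term, not a substance",
        "home-made preparation of poppy pods"
      )
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Walk ancestors of a concept
#'
#' @param ontology A `dao_ontology`.
#' @param id Concept id.
#' @return Character vector of ancestor ids from parent to root (excluding
#'   `id` itself); empty for a root concept.
#' @export
concept_ancestors <- function(ontology, id) {
  parent_of <- stats::setNames(ontology$concepts$parent_id,
                               ontology$concepts$id)
  out <- character()
  cur <- parent_of[[id]] %||% NA_character_
  while (!is.na(cur)) {
    if (cur %in% out) break # defensive; validated ontologies are acyclic
    out <- c(out, cur)
    cur <- parent_of[[cur]] %||% NA_character_
  }
  out
}

# Substance-type class used for reporting: the ancestor one level below the
# pharmacological root (so fentanyl resolves to the fentanyl-type subclass);
# a direct child of a root is its own class.
top_class_id <- function(ontology, id) {
  anc <- concept_ancestors(ontology, id)
  chain <- c(id, anc) # self towards root
  if (length(chain) <= 2L) return(id)
  chain[length(chain) - 1L]
}

#' Substance-type class of a concept
#'
#' Returns the label of the reporting class a substance concept belongs to:
#' the ancestor directly below its pharmacological root class, e.g. fentanyl
#' and its analogs resolve to the "fentanyl-type" subclass of the opioid
#' class, while a substance attached directly under the root (heroin,
#' buprenorphine) is its own class.
#'
#' @param ontology A `dao_ontology`.
#' @param id Concept id (vectorized).
#' @return Character vector of class labels.
#' @export
substance_class_of <- function(ontology, id) {
  vapply(id, function(i) {
    tc <- top_class_id(ontology, i)
    ontology$concepts$label[match(tc, ontology$concepts$id)]
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic digest of an ontology via its canonical Turtle form.
ontology_digest <- function(ontology) {
  rlang::hash(ontology_to_triples(ontology))
}
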