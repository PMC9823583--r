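DAO_NS  <- "http://daokit.org/dao#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"

term_type_predicate <- c(
  canonical        = "has_canonical_name",
  brand            = "has_brand_name",
  street           = "has_street_name",
  slang            = "has_slang_term",
  synonym          = "has_synonym",
  abbreviation     = "has_abbreviation",
  chemical_formula = "has_chemical_formula",
  lay_term         = "has_lay_term"
)
predicate_term_type <- stats::setNames(names(term_type_predicate),
                                       unname(term_type_predicate))

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

unescape_literal <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

fmt_num <- function(x) sprintf("%.15g", x)

# Flatten an ontology into a triple table (subject/predicate in prefixed
# form, literal flag distinguishing quoted objects from IRIs).
triples_of <- function(onto) {
  s <- character(); p <- character(); o <- character(); lit <- logical()
  add <- function(ss, pp, oo, ll) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo); lit <<- c(lit, ll)
  }
  co <- onto$concepts
  for (i in seq_len(nrow(co))) {
    id <- paste0("dao:", co$id[i])
    is_ind <- co$kind[i] == "substance_instance"
    add(id, "rdf:type", if (is_ind) "owl:NamedIndividual" else "owl:Class",
        FALSE)
    add(id, "rdfs:label", co$label[i], TRUE)
    add(id, "dao:concept_kind", co$kind[i], TRUE)
    if (!is.na(co$parent_id[i])) {
      if (is_ind) {
        add(id, "rdf:type", paste0("dao:", co$parent_id[i]), FALSE)
      } else {
        add(id, "rdfs:subClassOf", paste0("dao:", co$parent_id[i]), FALSE)
      }
    }
  }
  te <- onto$terms
  for (i in seq_len(nrow(te))) {
    id <- paste0("dao:", te$concept_id[i])
    pred <- paste0("dao:", term_type_predicate[[te$term_type[i]]])
    add(id, pred, te$surface[i], TRUE)
    if (isTRUE(te$case_sensitive[i])) {
      add(id, "dao:term_case_sensitive",
          paste0(te$term_type[i], "|", te$surface[i]), TRUE)
    }
  }
  un <- onto$units
  for (i in seq_len(nrow(un))) {
    id <- paste0("dao:", un$id[i])
    add(id, "rdf:type", "owl:Class", FALSE)
    add(id, "dao:canonical_unit_label", un$canonical_label[i], TRUE)
    add(id, "dao:unit_dimension", un$dimension[i], TRUE)
    if (!is.na(un$to_grams[i])) {
      add(id, "dao:grams_per_unit", fmt_num(un$to_grams[i]), TRUE)
    }
    for (sf in un$surface_forms[[i]]) {
      add(id, "dao:has_surface_form", sf, TRUE)
    }
  }
  for (pr in onto$object_properties) {
    add(paste0("dao:", pr), "rdf:type", "owl:ObjectProperty", FALSE)
  }
  for (pr in onto$data_properties) {
    add(paste0("dao:", pr), "rdf:type", "owl:DatatypeProperty", FALSE)
  }
  an <- onto$annotations
  for (i in seq_len(nrow(an))) {
    add(paste0("dao:", an$subject_id[i]), paste0("dao:", an$property[i]),
        an$value[i], TRUE)
  }
  tibble(subject = s, predicate = p, object = o, literal = lit)
}

# Canonical Turtle statement lines: one sorted triple per line.
ontology_to_triples <- function(onto) {
  tr <- triples_of(onto)
  if (!nrow(tr)) return(character())
  obj <- ifelse(tr$literal, paste0("\"", escape_literal(tr$object), "\""),
                tr$object)
  sort(paste0(tr$subject, " ", tr$predicate, " ", obj, " ."),
       method = "radix")
}

turtle_prefixes <- function() {
  c(
    paste0("@prefix dao: <", DAO_NS, "> ."),
    paste0("@prefix owl: <", OWL_NS, "> ."),
    paste0("@prefix rdf: <", RDF_NS, "> ."),
    paste0("@prefix rdfs: <", RDFS_NS, "> .")
  )
}

#' Serialize an ontology to RDF
#'
#' Writes the ontology as RDF using the package's fixed vocabulary: concepts
#' become `owl:Class` / `owl:NamedIndividual` resources with `rdfs:label`
#' and `rdfs:subClassOf` (or instance `rdf:type`) links, and term
#' attachments become data-property assertions named `has_brand_name`,
#' `has_street_name`, `has_slang_term`, `has_synonym`,
#' `has_chemical_formula`, `has_abbreviation` and `has_lay_term`.
#'
#' Turtle output is canonical: a fixed prefix block followed by one triple
#' per line in byte-sorted order, so equal ontologies serialize to identical
#' bytes and diffs are meaningful.
#'
#' @param ontology A `dao_ontology`.
#' @param path Output file path.
#' @param dialect `"turtle"` (default) or `"rdf_xml"`.
#' @return `path`, invisibly.
#' @seealso [load_ontology()]
#' @export
save_ontology <- function(ontology, path, dialect = c("turtle", "rdf_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "turtle") {
    lines <- c(turtle_prefixes(), "", ontology_to_triples(ontology))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    write_rdf_xml(ontology, path)
  }
  invisible(path)
}

expand_prefixed <- function(x) {
  x <- sub("^dao:", DAO_NS, x)
  x <- sub("^owl:", OWL_NS, x)
  x <- sub("^rdf:", RDF_NS, x)
  x <- sub("^rdfs:", RDFS_NS, x)
  x
}

write_rdf_xml <- function(ontology, path) {
  tr <- triples_of(ontology)
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS,
    "xmlns:owl" = OWL_NS, "xmlns:dao" = DAO_NS
  )
  for (subj in unique(tr$subject)) {
    node <- xml2::xml_add_child(doc, "rdf:Description",
                                "rdf:about" = expand_prefixed(subj))
    rows <- tr[tr$subject == subj, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      if (rows$literal[i]) {
        xml2::xml_add_child(node, rows$predicate[i], rows$object[i])
      } else {
        xml2::xml_add_child(node, rows$predicate[i],
                            "rdf:resource" = expand_prefixed(rows$object[i]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

compact_iri <- function(x) {
  x <- sub(DAO_NS, "dao:", x, fixed = TRUE)
  x <- sub(OWL_NS, "owl:", x, fixed = TRUE)
  x <- sub(RDF_NS, "rdf:", x, fixed = TRUE)
  x <- sub(RDFS_NS, "rdfs:", x, fixed = TRUE)
  x
}

parse_turtle_triples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix") &
                   !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s+(.*)\\s*\\.$", lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(paste0("cannot parse Turtle statement: ", lines[bad][1]),
          class = "dao_format_error")
  }
  s <- vapply(m, `[[`, "", 2)
  p <- vapply(m, `[[`, "", 3)
  raw_o <- trimws(vapply(m, `[[`, "", 4))
  lit <- startsWith(raw_o, "\"")
  o <- raw_o
  if (any(lit)) {
    lm <- regmatches(raw_o[lit],
                     regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"", raw_o[lit]))
    ok <- vapply(lm, length, integer(1)) == 2L
    if (!all(ok)) {
      abort("malformed literal in Turtle input", class = "dao_format_error")
    }
    o[lit] <- unescape_literal(vapply(lm, `[[`, "", 2))
  }
  tibble(subject = s, predicate = p, object = o, literal = lit)
}

parse_rdf_xml_triples <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("cannot parse RDF/XML: ", conditionMessage(e)),
          class = "dao_format_error")
  })
  descs <- xml2::xml_find_all(doc, "./rdf:Description")
  out <- lapply(descs, function(node) {
    subj <- compact_iri(xml2::xml_attr(node, "about"))
    kids <- xml2::xml_children(node)
    res <- xml2::xml_attr(kids, "resource")
    lit <- is.na(res)
    tibble(
      subject = subj,
      predicate = vapply(kids, function(k) {
        nm <- xml2::xml_name(k, ns = xml2::xml_ns(doc))
        # xml_name with ns gives e.g. "rdfs:label" under declared prefixes
        nm
      }, character(1)),
      object = ifelse(lit, xml2::xml_text(kids), compact_iri(res)),
      literal = lit
    )
  })
  dplyr::bind_rows(out)
}

local_name <- function(x) sub("^dao:", "", x)

triples_to_ontology <- function(tr) {
  is_type <- tr$predicate == "rdf:type" & !tr$literal
  data_props <- local_name(tr$subject[is_type &
                                        tr$object == "owl:DatatypeProperty"])
  obj_props <- local_name(tr$subject[is_type &
                                       tr$object == "owl:ObjectProperty"])
  unit_subjects <- unique(tr$subject[tr$predicate == "dao:unit_dimension"])
  declared <- unique(tr$subject[is_type &
                                  tr$object %in% c("owl:Class",
                                                   "owl:NamedIndividual")])
  concept_subjects <- setdiff(declared, unit_subjects)

  get1 <- function(subj, pred) {
    v <- tr$object[tr$subject == subj & tr$predicate == pred]
    if (length(v)) v[1] else NA_character_
  }
  getn <- function(subj, pred) {
    tr$object[tr$subject == subj & tr$predicate == pred]
  }

  concepts <- dplyr::bind_rows(lapply(concept_subjects, function(subj) {
    kind <- get1(subj, "dao:concept_kind")
    is_ind <- "owl:NamedIndividual" %in% getn(subj, "rdf:type")
    parent <- if (is_ind) {
      tp <- setdiff(getn(subj, "rdf:type"),
                    c("owl:NamedIndividual", "owl:Class"))
      if (length(tp)) local_name(tp[1]) else NA_character_
    } else {
      sc <- getn(subj, "rdfs:subClassOf")
      if (length(sc)) local_name(sc[1]) else NA_character_
    }
    tibble(
      id = local_name(subj),
      label = get1(subj, "rdfs:label"),
      kind = if (is.na(kind) && is_ind) "substance_instance" else kind,
      parent_id = parent
    )
  }))
  if (is.null(concepts) || !nrow(concepts)) concepts <- empty_concepts()

  cs_keys <- paste0(local_name(tr$subject), "\r",
                    tr$object)[tr$predicate == "dao:term_case_sensitive"]
  term_rows <- tr[tr$predicate %in% paste0("dao:",
                                           names(predicate_term_type)) &
                    tr$literal, , drop = FALSE]
  terms <- if (nrow(term_rows)) {
    tt <- predicate_term_type[sub("^dao:", "", term_rows$predicate)]
    tibble(
      concept_id = local_name(term_rows$subject),
      surface = term_rows$object,
      term_type = unname(tt),
      case_sensitive = paste0(local_name(term_rows$subject), "\r",
                              tt, "|", term_rows$object) %in% cs_keys
    )
  } else {
    empty_terms()
  }

  units <- dplyr::bind_rows(lapply(unit_subjects, function(subj) {
    g <- get1(subj, "dao:grams_per_unit")
    tibble(
      id = local_name(subj),
      canonical_label = get1(subj, "dao:canonical_unit_label"),
      dimension = get1(subj, "dao:unit_dimension"),
      to_grams = if (is.na(g)) NA_real_ else as.numeric(g),
      surface_forms = list(getn(subj, "dao:has_surface_form"))
    )
  }))
  if (is.null(units) || !nrow(units)) units <- empty_units()

  known_preds <- c(
    "rdf:type", "rdfs:label", "rdfs:subClassOf", "dao:concept_kind",
    "dao:canonical_unit_label", "dao:unit_dimension", "dao:grams_per_unit",
    "dao:has_surface_form", "dao:term_case_sensitive",
    paste0("dao:", names(predicate_term_type))
  )
  ann_rows <- tr[!(tr$predicate %in% known_preds) & tr$literal, ,
                 drop = FALSE]
  annotations <- if (nrow(ann_rows)) {
    tibble(
      subject_id = local_name(ann_rows$subject),
      property = sub("^(dao:|rdfs:|rdf:|owl:)", "", ann_rows$predicate),
      value = ann_rows$object
    )
  } else {
    empty_annotations()
  }

  dao_ontology(
    concepts = concepts, terms = terms, units = units,
    object_properties = obj_props, data_properties = data_props,
    annotations = annotations
  )
}

#' Load an ontology from RDF
#'
#' Reads a Turtle or RDF/XML file written with [save_ontology()] (or any
#' file using the same vocabulary). Properties outside the package
#' vocabulary are preserved as annotation triples. Structural-invariant
#' violations (a term attached to a missing concept, a parent cycle) raise
#' an integrity error; unparseable input raises a format error.
#'
#' @param path Input file path.
#' @param dialect `"turtle"` or `"rdf_xml"`; by default inferred from the
#'   file extension (`.owl`, `.rdf`, `.xml` read as RDF/XML, anything else
#'   as Turtle).
#' @return A validated `dao_ontology`.
#' @examples
#' f <- tempfile(fileext = ".ttl")
#' save_ontology(build_fixture_dao(), f)
#' onto <- load_ontology(f)
#' @export
load_ontology <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "dao_format_error")
  }
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("owl", "rdf", "xml")) "rdf_xml" else "turtle"
  }
  dialect <- match.arg(dialect, c("turtle", "rdf_xml"))
  tr <- if (dialect == "turtle") parse_turtle_triples(path) else
    parse_rdf_xml_triples(path)
  triples_to_ontology(tr)
}
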