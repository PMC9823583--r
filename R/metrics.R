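#' Structural metrics of an ontology
#'
#' Counts the axioms an OWL rendering of the ontology would contain:
#' declaration axioms (one per declared class, individual, object property
#' and data property; unit concepts are dosage classes and count as
#' classes), logical axioms (subclass links between classes, class
#' assertions linking individuals to their classes, and data-property
#' assertions for term attachments and unit surface forms), and annotation
#' assertions. The combined axiom count is their sum.
#'
#' @param ontology A `dao_ontology`.
#' @return An object of class `dao_metrics` (a named list of non-negative
#'   integer counts) with [generics::tidy()] and [generics::glance()]
#'   methods.
#' @examples
#' m <- compute_metrics(build_fixture_dao())
#' generics::tidy(m)
#' @export
compute_metrics <- function(ontology) {
  co <- ontology$concepts
  un <- ontology$units
  is_ind <- co$kind == "substance_instance"
  class_count <- sum(!is_ind) + nrow(un)
  individual_count <- sum(is_ind)
  object_property_count <- length(ontology$object_properties)
  data_property_count <- length(ontology$data_properties)

  has_parent <- !is.na(co$parent_id)
  parent_is_ind <- co$parent_id %in% co$id[is_ind]
  subclassof_count <- sum(has_parent & !is_ind)
  class_assertion_count <- sum(has_parent & is_ind)
  data_property_assertion_count <- nrow(ontology$terms) +
    sum(lengths(un$surface_forms))
  annotation_assertion_count <- nrow(ontology$annotations)

  declaration_axiom_count <- class_count + individual_count +
    object_property_count + data_property_count
  logical_axiom_count <- subclassof_count + class_assertion_count +
    data_property_assertion_count
  axiom_count <- logical_axiom_count + declaration_axiom_count +
    annotation_assertion_count

  structure(
    list(
      axiom_count = axiom_count,
      logical_axiom_count = logical_axiom_count,
      declaration_axiom_count = declaration_axiom_count,
      class_count = class_count,
      object_property_count = object_property_count,
      data_property_count = data_property_count,
      individual_count = individual_count,
      subclassof_count = subclassof_count,
      data_property_assertion_count = data_property_assertion_count,
      class_assertion_count = class_assertion_count,
      annotation_assertion_count = annotation_assertion_count
    ),
    class = "dao_metrics"
  )
}

#' @export
print.dao_metrics <- function(x, ...) {
  nm <- names(x)
  w <- max(nchar(nm))
  for (i in seq_along(x)) {
    cat(formatC(nm[i], width = w, flag = "-"), " ", x[[i]], "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compute_metrics
#' @param x A `dao_metrics` object.
#' @param ... Unused.
#' @export
tidy.dao_metrics <- function(x, ...) {
  tibble(metric = names(x), count = as.integer(unlist(x)))
}

#' @rdname compute_metrics
#' @export
glance.dao_metrics <- function(x, ...) {
  as_tibble(lapply(unclass(x), as.integer))
}

#' @rdname compute_metrics
#' @param object A `dao_metrics` object.
#' @export
autoplot.dao_metrics <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$metric,
                                                     .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
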