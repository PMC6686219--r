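# Raw counts feeding the metrics: axiom, element and feature censuses plus
# the DL-profile violation count.

#' Count logical and non-logical axioms
#'
#' Axioms are partitioned by the OWL structural classification: entity
#' declarations and annotation axioms are non-logical, everything else
#' (class axioms, property axioms, assertions, keys, datatype definitions)
#' is logical.  The total feeds the lawfulness denominator.
#'
#' @param model An `ontology_model`.
#' @return List with `n_logical`, `n_non_logical`, `n_total`.
#' @export
census_axioms <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  logical_n <- sum(vapply(model$axioms, is_logical_axiom, TRUE))
  total <- length(model$axioms)
  structure(list(
    n_logical = as.integer(logical_n),
    n_non_logical = as.integer(total - logical_n),
    n_total = as.integer(total)
  ), class = "axiom_census")
}

#' Count declared named elements
#'
#' Elements are the declared named classes, individuals, object properties
#' and data properties; anonymous expressions are excluded.  Their sum is
#' the numerator of the comprehensiveness score.
#'
#' @param model An `ontology_model`.
#' @return List with the four per-kind counts and their sum `n_elements`.
#' @export
census_elements <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  e <- model$entities
  out <- list(
    n_classes = length(e$classes),
    n_individuals = length(e$individuals),
    n_object_properties = length(e$object_properties),
    n_data_properties = length(e$data_properties)
  )
  out$n_elements <- out$n_classes + out$n_individuals +
    out$n_object_properties + out$n_data_properties
  structure(lapply(out, as.integer), class = "element_census")
}

#' Survey which OWL constructs an ontology uses
#'
#' Scans every axiom (and, recursively, every class expression inside axiom
#' payloads) and marks each construct of the fixed 39-item catalog that
#' occurs at least once.  Invariant under re-ordering of the input axioms.
#'
#' @param model An `ontology_model`.
#' @return List with `catalog` (the 39 identifiers) and `used` (the subset
#'   observed).
#' @seealso [owl_feature_catalog()], [richness()]
#' @export
survey_features <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  catalog <- owl_feature_catalog()
  seen <- character()
  for (ax in model$axioms) {
    seen <- c(seen, ax$type,
              unlist(lapply(axiom_expressions(ax), ce_constructs)))
  }
  structure(list(
    catalog = catalog,
    used = catalog[catalog %in% unique(seen)]
  ), class = "feature_inventory")
}

#' Count OWL 2 DL profile violations
#'
#' Applies a documented subset of the OWL 2 DL global restrictions:
#' \itemize{
#'   \item illegal punning of an IRI as both a class and a datatype;
#'   \item declaring an entity inside the reserved vocabulary namespaces
#'     (rdf, rdfs, owl, xsd);
#'   \item use of an undeclared property IRI as a predicate;
#'   \item a transitive (non-simple) property inside a cardinality
#'     restriction.
#' }
#' Each offending IRI (or restriction occurrence) counts once.  Only the
#' count feeds the lawfulness score.
#'
#' @param model An `ontology_model`.
#' @return Non-negative integer violation count.
#' @export
count_dl_violations <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  n <- 0L
  # class/datatype punning
  n <- n + length(intersect(model$entities$classes, model$datatypes))
  # reserved-vocabulary entity declarations
  all_entities <- unlist(model$entities, use.names = FALSE)
  reserved <- vapply(all_entities, function(e) {
    any(vapply(RESERVED_NS, function(ns) startsWith(e, ns), TRUE)) &&
      !identical(e, IRI_OWL_THING)
  }, TRUE)
  n <- n + sum(reserved)
  # undeclared property predicates
  n <- n + length(model$undeclared_properties)
  # transitive property inside a cardinality restriction
  transitive <- vapply(
    Filter(function(a) a$type == "TransitiveObjectProperty", model$axioms),
    function(a) a$property, "")
  if (length(transitive)) {
    card_props <- function(ce) {
      if (is.character(ce) || is.null(ce)) return(character())
      own <- if (ce$type %in% c("ObjectMinCardinality", "ObjectMaxCardinality",
                                "ObjectExactCardinality")) ce$property
             else character()
      kids <- switch(ce$type,
        ObjectIntersectionOf = , ObjectUnionOf = ce$operands,
        ObjectComplementOf = list(ce$operand),
        ObjectSomeValuesFrom = , ObjectAllValuesFrom = list(ce$filler),
        list())
      c(own, unlist(lapply(kids, card_props)))
    }
    used_in_card <- unlist(lapply(model$axioms, function(ax) {
      unlist(lapply(axiom_expressions(ax), card_props))
    }))
    n <- n + sum(used_in_card %in% transitive)
  }
  as.integer(n)
}

#' Extract raw entity labels
#'
#' One record per entity per selected label.  Label selection follows the
#' language preference order; among labels of equal preference the first in
#' sorted order wins, so extraction is deterministic.  Entities without any
#' matching label fall back to the humanized IRI fragment.
#'
#' @param model An `ontology_model`.
#' @param label_properties Annotation property IRIs to read labels from;
#'   defaults to `rdfs:label`.  `skos:prefLabel` is the documented opt-in.
#' @param language_preference Language tags in preference order; `""` is
#'   the untagged literal.  Default prefers untagged, then `"en"`.
#' @return Data frame with columns `entity_iri`, `raw_label`.  The fallback
#'   raw label for unlabeled entities is the verbatim IRI fragment; camel
#'   case and separators are handled downstream by the normalization
#'   pipeline.
#' @export
extract_labels <- function(model,
                           label_properties = IRI_RDFS_LABEL,
                           language_preference = c("", "en")) {
  stopifnot(inherits(model, "ontology_model"))
  entities <- unlist(model$entities, use.names = FALSE)
  lab <- model$label_annotations
  lab <- lab[lab$property %in% label_properties, , drop = FALSE]
  pick <- function(iri) {
    cand <- lab[lab$iri == iri, , drop = FALSE]
    if (nrow(cand) == 0L) return(iri_fragment(iri))
    pref <- match(cand$lang, language_preference)
    pref[is.na(pref)] <- length(language_preference) + 1L
    cand <- cand[order(pref, cand$value), , drop = FALSE]
    cand$value[[1L]]
  }
  data.frame(
    entity_iri = entities,
    raw_label = vapply(entities, pick, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
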