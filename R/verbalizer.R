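# Template-based verbalization of logical axioms into English, so domain
# experts can judge statements as true or false without reading OWL.  One
# template per supported axiom type; class expressions render recursively.
# Sentences are pure functions of (axiom, label_map) and never contain a
# raw URI.

#' Surface text for an entity
#'
#' Uses the entity's processed label when one is available; otherwise the
#' humanized IRI fragment (camel case split, separators to spaces,
#' lowercased).  Raw URIs never reach a sentence.
#'
#' @param iri Absolute entity IRI.
#' @param label_map Named character vector mapping IRIs to processed
#'   labels.
#' @return Surface text.
#' @export
#' @examples
#' render_entity("http://ex.org/onto#HeartAttack", c())  # "heart attack"
render_entity <- function(iri, label_map = character()) {
  idx <- match(iri, names(label_map))
  if (!is.na(idx)) {
    lbl <- label_map[[idx]]
    if (nzchar(lbl) && !identical(lbl, EMPTY_AFTER_PROCESSING)) return(lbl)
  }
  humanize_fragment(iri_fragment(iri))
}

render_literal_en <- function(lit) paste0("\"", lit$value, "\"")

# Noun-phrase-ish rendering of a class expression.
ce_phrase <- function(ce, label_map) {
  ent <- function(x) render_entity(x, label_map)
  if (is.character(ce)) {
    if (identical(ce, IRI_OWL_THING)) return("thing")
    return(ent(ce))
  }
  switch(ce$type,
    ObjectIntersectionOf = paste(
      vapply(ce$operands, ce_phrase, "", label_map = label_map),
      collapse = " and "),
    ObjectUnionOf = paste(
      vapply(ce$operands, ce_phrase, "", label_map = label_map),
      collapse = " or "),
    ObjectComplementOf = paste0(
      "something that is not ",
      with_article(ce_phrase(ce$operand, label_map))),
    ObjectOneOf = paste0("one of ",
                         paste(vapply(ce$individuals, ent, ""),
                               collapse = ", ")),
    ObjectSomeValuesFrom = paste0(
      "something that ", ent(ce$property), " ",
      with_article(ce_phrase(ce$filler, label_map))),
    ObjectAllValuesFrom = paste0(
      "something that ", ent(ce$property), " only ",
      plural_ish(ce_phrase(ce$filler, label_map))),
    ObjectHasValue = paste0("something that ", ent(ce$property), " ",
                            ent(ce$individual)),
    ObjectMinCardinality = card_phrase("at least", ce, label_map),
    ObjectMaxCardinality = card_phrase("at most", ce, label_map),
    ObjectExactCardinality = card_phrase("exactly", ce, label_map),
    DataSomeValuesFrom = paste0("something that has some ",
                                ent(ce$property), " value"),
    abort_ontoqc(sprintf("no phrase template for expression '%s'", ce$type),
                 "ontoqc_data_error")
  )
}

with_article <- function(phrase) {
  if (phrase %in% c("thing", "something")) return("something")
  # complex phrases already carry their own determiner
  if (grepl("^(something|one of|not )", phrase)) return(phrase)
  paste(article_for(phrase), phrase)
}

plural_ish <- function(phrase) phrase

card_phrase <- function(qualifier, ce, label_map) {
  ent <- function(x) render_entity(x, label_map)
  filler <- if (is.null(ce$filler)) "things"
            else plural_ish(ce_phrase(ce$filler, label_map))
  paste0("something that ", ent(ce$property), " ", qualifier, " ",
         ce$n, " ", filler)
}

capitalize <- function(s) {
  paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
}

#' Verbalize one logical axiom
#'
#' Renders the axiom through its English template.  Supported types are
#' the 25 returned by [supported_axiom_types()]; any other logical axiom
#' yields `NULL` (the unsupported marker, tallied by
#' [verbalize_ontology()]).
#'
#' @param ax An `owl_axiom`.
#' @param label_map Named character vector mapping IRIs to processed
#'   labels.
#' @return A list with `statement_id`, `axiom_type`, `sentence`, `source`
#'   (the canonical axiom form), or `NULL` when unsupported.
#' @export
verbalize_axiom <- function(ax, label_map = character()) {
  stopifnot(inherits(ax, "owl_axiom"))
  if (!ax$type %in% supported_axiom_types()) return(NULL)
  ent <- function(x) render_entity(x, label_map)
  ph <- function(ce) ce_phrase(ce, label_map)
  art <- function(ce) with_article(ph(ce))
  body <- switch(ax$type,
    SubClassOf = sprintf("every %s is %s", ph(ax$sub), art(ax$sup)),
    EquivalentClasses = sprintf("every %s is %s, and vice versa",
                                ph(ax$classes[[1L]]), art(ax$classes[[2L]])),
    DisjointClasses = sprintf("no %s is %s", ph(ax$classes[[1L]]),
                              art(ax$classes[[2L]])),
    SubObjectPropertyOf = sprintf(
      "if one thing %s another, then the first also %s the second",
      ent(ax$sub), ent(ax$sup)),
    EquivalentObjectProperties = sprintf(
      "one thing %s another exactly when it %s it",
      ent(ax$properties[[1L]]), ent(ax$properties[[2L]])),
    InverseObjectProperties = sprintf(
      "if one thing %s another, then the second %s the first",
      ent(ax$first), ent(ax$second)),
    ObjectPropertyDomain = sprintf("anything that %s something is %s",
                                   ent(ax$property), art(ax$ce)),
    ObjectPropertyRange = sprintf("anything that something %s is %s",
                                  ent(ax$property), art(ax$ce)),
    FunctionalObjectProperty = sprintf("anything %s at most one thing",
                                       ent(ax$property)),
    InverseFunctionalObjectProperty = sprintf(
      "at most one thing %s any given thing", ent(ax$property)),
    ReflexiveObjectProperty = sprintf("everything %s itself",
                                      ent(ax$property)),
    IrreflexiveObjectProperty = sprintf("nothing %s itself",
                                        ent(ax$property)),
    SymmetricObjectProperty = sprintf(
      "if one thing %s another, then the second also %s the first",
      ent(ax$property), ent(ax$property)),
    AsymmetricObjectProperty = sprintf(
      "if one thing %s another, then the second cannot %s the first",
      ent(ax$property), ent(ax$property)),
    TransitiveObjectProperty = sprintf(
      "if one thing %s a second, and the second %s a third, then the first %s the third",
      ent(ax$property), ent(ax$property), ent(ax$property)),
    SubDataPropertyOf = sprintf(
      "anything with a %s value also has it as a %s value",
      ent(ax$sub), ent(ax$sup)),
    DataPropertyDomain = sprintf("anything with a %s value is %s",
                                 ent(ax$property), art(ax$ce)),
    DataPropertyRange = sprintf("every %s value is %s",
                                ent(ax$property), art(ax$range)),
    FunctionalDataProperty = sprintf("anything has at most one %s value",
                                     ent(ax$property)),
    SameIndividual = sprintf("%s and %s are the same thing",
                             ent(ax$individuals[[1L]]),
                             ent(ax$individuals[[2L]])),
    DifferentIndividuals = sprintf(
      "%s are all different from one another",
      paste(vapply(ax$individuals, ent, ""), collapse = " and ")),
    ClassAssertion = sprintf("%s is %s", ent(ax$individual), art(ax$ce)),
    ObjectPropertyAssertion = sprintf("%s %s %s", ent(ax$subject),
                                      ent(ax$property), ent(ax$object)),
    DataPropertyAssertion = sprintf("the %s of %s is %s", ent(ax$property),
                                    ent(ax$subject),
                                    render_literal_en(ax$value)),
    HasKey = sprintf("each %s is uniquely identified by %s", ph(ax$class),
                     paste(vapply(ax$properties, ent, ""),
                           collapse = " and "))
  )
  canon <- axiom_functional(ax)
  list(
    statement_id = hash_hex(canon),
    axiom_type = ax$type,
    sentence = paste0(capitalize(body), "."),
    source = canon
  )
}

#' Verbalize every logical axiom of an ontology
#'
#' Produces one statement per supported logical axiom, ordered by
#' `statement_id` so output is stable across runs.  The accounting
#' invariant `nrow(statements) + n_unsupported == n_logical` always holds.
#'
#' @param model An `ontology_model`.
#' @param options,label_properties,language_preference Label-pipeline
#'   settings used to build the surface forms.
#' @return List of class `statement_set` with `ontology_iri`, `statements`
#'   (data frame: `statement_id`, `axiom_type`, `sentence`, `source`) and
#'   `n_unsupported`.
#' @export
verbalize_ontology <- function(model, options = parse_options(),
                               label_properties = IRI_RDFS_LABEL,
                               language_preference = c("", "en")) {
  stopifnot(inherits(model, "ontology_model"))
  recs <- label_records(model, options, label_properties,
                       language_preference)
  label_map <- stats::setNames(recs$processed_label, recs$entity_iri)
  logical_axioms <- Filter(is_logical_axiom, model$axioms)
  rendered <- lapply(logical_axioms, verbalize_axiom, label_map = label_map)
  supported <- rendered[!vapply(rendered, is.null, TRUE)]
  statements <- if (length(supported)) {
    df <- data.frame(
      statement_id = vapply(supported, `[[`, "", "statement_id"),
      axiom_type = vapply(supported, `[[`, "", "axiom_type"),
      sentence = vapply(supported, `[[`, "", "sentence"),
      source = vapply(supported, `[[`, "", "source"),
      stringsAsFactors = FALSE)
    df[order(df$statement_id), , drop = FALSE]
  } else {
    data.frame(statement_id = character(), axiom_type = character(),
               sentence = character(), source = character(),
               stringsAsFactors = FALSE)
  }
  rownames(statements) <- NULL
  structure(list(
    ontology_iri = model$ontology_iri,
    statements = statements,
    n_unsupported = length(logical_axioms) - length(supported)
  ), class = "statement_set")
}

#' @export
print.statement_set <- function(x, ...) {
  cat(sprintf("<statement_set> %d statements, %d unsupported logical axioms\n",
              nrow(x$statements), x$n_unsupported))
  invisible(x)
}
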