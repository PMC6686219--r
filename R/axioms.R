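# In-memory axiom and class-expression representation.
#
# An axiom is a list with a `type` tag from the closed enumeration in
# constants.R plus a typed payload.  A class expression is either a
# character IRI (named class) or a list with a `type` tag from
# EXPRESSION_TYPES.  Literals are list(value=, lang=, datatype=).

axiom <- function(type, ...) {
  if (!type %in% AXIOM_TYPES) {
    abort_ontoqc(sprintf("unknown axiom type '%s'", type),
                 "ontoqc_data_error")
  }
  structure(list(type = type, ...), class = "owl_axiom")
}

owl_literal <- function(value, lang = "", datatype = "") {
  list(value = value, lang = lang, datatype = datatype)
}

is_literal <- function(x) is.list(x) && !is.null(x$value) && is.null(x$type)

#' @export
print.owl_axiom <- function(x, ...) {
  cat(axiom_functional(x), "\n")
  invisible(x)
}

render_literal_fs <- function(lit) {
  out <- paste0("\"", lit$value, "\"")
  if (nzchar(lit$lang %||% "")) out <- paste0(out, "@", lit$lang)
  if (nzchar(lit$datatype %||% "")) out <- paste0(out, "^^<", lit$datatype, ">")
  out
}

render_ce_fs <- function(ce) {
  if (is.character(ce)) return(paste0("<", ce, ">"))
  switch(ce$type,
    ObjectIntersectionOf = ,
    ObjectUnionOf = sprintf(
      "%s(%s)", ce$type,
      paste(sort(vapply(ce$operands, render_ce_fs, "")), collapse = " ")),
    ObjectComplementOf = sprintf("ObjectComplementOf(%s)",
                                 render_ce_fs(ce$operand)),
    ObjectOneOf = sprintf(
      "ObjectOneOf(%s)",
      paste(sort(sprintf("<%s>", unlist(ce$individuals))), collapse = " ")),
    ObjectSomeValuesFrom = ,
    ObjectAllValuesFrom = sprintf("%s(<%s> %s)", ce$type, ce$property,
                                  render_ce_fs(ce$filler)),
    ObjectHasValue = sprintf("ObjectHasValue(<%s> <%s>)", ce$property,
                             ce$individual),
    ObjectMinCardinality = ,
    ObjectMaxCardinality = ,
    ObjectExactCardinality = sprintf(
      "%s(%d <%s>%s)", ce$type, ce$n, ce$property,
      if (is.null(ce$filler)) "" else paste0(" ", render_ce_fs(ce$filler))),
    DataSomeValuesFrom = sprintf("DataSomeValuesFrom(<%s> <%s>)",
                                 ce$property, ce$range),
    abort_ontoqc(sprintf("unknown class expression type '%s'", ce$type),
                 "ontoqc_data_error")
  )
}

# Canonical OWL functional-syntax-style rendering; unordered arguments are
# sorted so logically identical axioms render identically.  Used for
# de-duplication and as the statement_id hash input.
axiom_functional <- function(ax) {
  set <- function(xs) paste(sort(vapply(xs, render_ce_fs, "")), collapse = " ")
  iset <- function(xs) paste(sort(sprintf("<%s>", unlist(xs))), collapse = " ")
  switch(ax$type,
    Declaration = sprintf("Declaration(%s(<%s>))", ax$entity_kind, ax$iri),
    SubClassOf = sprintf("SubClassOf(%s %s)", render_ce_fs(ax$sub),
                         render_ce_fs(ax$sup)),
    EquivalentClasses = sprintf("EquivalentClasses(%s)", set(ax$classes)),
    DisjointClasses = sprintf("DisjointClasses(%s)", set(ax$classes)),
    DisjointUnion = sprintf("DisjointUnion(<%s> %s)", ax$class,
                            set(ax$disjuncts)),
    SubObjectPropertyOf = sprintf("SubObjectPropertyOf(<%s> <%s>)", ax$sub,
                                  ax$sup),
    EquivalentObjectProperties = sprintf("EquivalentObjectProperties(%s)",
                                         iset(ax$properties)),
    DisjointObjectProperties = sprintf("DisjointObjectProperties(%s)",
                                       iset(ax$properties)),
    InverseObjectProperties = sprintf("InverseObjectProperties(%s)",
                                      iset(list(ax$first, ax$second))),
    ObjectPropertyDomain = sprintf("ObjectPropertyDomain(<%s> %s)",
                                   ax$property, render_ce_fs(ax$ce)),
    ObjectPropertyRange = sprintf("ObjectPropertyRange(<%s> %s)",
                                  ax$property, render_ce_fs(ax$ce)),
    FunctionalObjectProperty = ,
    InverseFunctionalObjectProperty = ,
    ReflexiveObjectProperty = ,
    IrreflexiveObjectProperty = ,
    SymmetricObjectProperty = ,
    AsymmetricObjectProperty = ,
    TransitiveObjectProperty = ,
    FunctionalDataProperty = sprintf("%s(<%s>)", ax$type, ax$property),
    SubDataPropertyOf = sprintf("SubDataPropertyOf(<%s> <%s>)", ax$sub,
                                ax$sup),
    EquivalentDataProperties = sprintf("EquivalentDataProperties(%s)",
                                       iset(ax$properties)),
    DisjointDataProperties = sprintf("DisjointDataProperties(%s)",
                                     iset(ax$properties)),
    DataPropertyDomain = sprintf("DataPropertyDomain(<%s> %s)", ax$property,
                                 render_ce_fs(ax$ce)),
    DataPropertyRange = sprintf("DataPropertyRange(<%s> <%s>)", ax$property,
                                ax$range),
    SameIndividual = sprintf("SameIndividual(%s)", iset(ax$individuals)),
    DifferentIndividuals = sprintf("DifferentIndividuals(%s)",
                                   iset(ax$individuals)),
    ClassAssertion = sprintf("ClassAssertion(%s <%s>)", render_ce_fs(ax$ce),
                             ax$individual),
    ObjectPropertyAssertion = sprintf(
      "ObjectPropertyAssertion(<%s> <%s> <%s>)", ax$property, ax$subject,
      ax$object),
    NegativeObjectPropertyAssertion = sprintf(
      "NegativeObjectPropertyAssertion(<%s> <%s> <%s>)", ax$property,
      ax$subject, ax$object),
    DataPropertyAssertion = sprintf(
      "DataPropertyAssertion(<%s> <%s> %s)", ax$property, ax$subject,
      render_literal_fs(ax$value)),
    NegativeDataPropertyAssertion = sprintf(
      "NegativeDataPropertyAssertion(<%s> <%s> %s)", ax$property, ax$subject,
      render_literal_fs(ax$value)),
    HasKey = sprintf("HasKey(<%s> %s)", ax$class, iset(ax$properties)),
    DatatypeDefinition = sprintf("DatatypeDefinition(<%s> <%s>)",
                                 ax$datatype, ax$datarange),
    AnnotationAssertion = sprintf(
      "AnnotationAssertion(<%s> <%s> %s)", ax$property, ax$subject,
      if (is_literal(ax$value)) render_literal_fs(ax$value)
      else paste0("<", ax$value, ">")),
    SubAnnotationPropertyOf = sprintf("SubAnnotationPropertyOf(<%s> <%s>)",
                                      ax$sub, ax$sup),
    AnnotationPropertyDomain = sprintf("AnnotationPropertyDomain(<%s> <%s>)",
                                       ax$property, ax$iri),
    AnnotationPropertyRange = sprintf("AnnotationPropertyRange(<%s> <%s>)",
                                      ax$property, ax$iri),
    abort_ontoqc(sprintf("cannot render axiom type '%s'", ax$type),
                 "ontoqc_data_error")
  )
}

is_logical_axiom <- function(ax) ax$type %in% AXIOM_TYPES_LOGICAL

# All class-expression construct tags occurring in an expression tree.
ce_constructs <- function(ce) {
  if (is.character(ce) || is.null(ce)) return(character())
  kids <- switch(ce$type,
    ObjectIntersectionOf = ,
    ObjectUnionOf = ce$operands,
    ObjectComplementOf = list(ce$operand),
    ObjectSomeValuesFrom = ,
    ObjectAllValuesFrom = list(ce$filler),
    ObjectMinCardinality = ,
    ObjectMaxCardinality = ,
    ObjectExactCardinality = if (is.null(ce$filler)) list() else
      list(ce$filler),
    list()
  )
  unique(c(ce$type, unlist(lapply(kids, ce_constructs))))
}

# Expression payload slots per axiom type (for feature survey and checks).
axiom_expressions <- function(ax) {
  switch(ax$type,
    SubClassOf = list(ax$sub, ax$sup),
    EquivalentClasses = ,
    DisjointClasses = ax$classes,
    DisjointUnion = c(list(ax$class), ax$disjuncts),
    ObjectPropertyDomain = ,
    ObjectPropertyRange = ,
    DataPropertyDomain = list(ax$ce),
    ClassAssertion = list(ax$ce),
    list()
  )
}
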