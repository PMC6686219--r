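# Vocabulary IRIs and the fixed construct catalogs that every metric
# denominates against.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"

IRI_RDF_TYPE    <- paste0(RDF_NS, "type")
IRI_RDF_FIRST   <- paste0(RDF_NS, "first")
IRI_RDF_REST    <- paste0(RDF_NS, "rest")
IRI_RDF_NIL     <- paste0(RDF_NS, "nil")
IRI_RDFS_LABEL  <- paste0(RDFS_NS, "label")
IRI_SKOS_PREFLABEL <- paste0(SKOS_NS, "prefLabel")
IRI_OWL_THING   <- paste0(OWL_NS, "Thing")

RESERVED_NS <- c(RDF_NS, RDFS_NS, OWL_NS, XSD_NS)

# Axiom-type tags form a closed enumeration.  The split into logical and
# non-logical follows the OWL 2 structural specification: declarations and
# annotation axioms carry no entailment semantics, everything else does.
AXIOM_TYPES_LOGICAL <- c(
  # class axioms
  "SubClassOf", "EquivalentClasses", "DisjointClasses", "DisjointUnion",
  # object property axioms
  "SubObjectPropertyOf", "EquivalentObjectProperties",
  "DisjointObjectProperties", "InverseObjectProperties",
  "ObjectPropertyDomain", "ObjectPropertyRange",
  "FunctionalObjectProperty", "InverseFunctionalObjectProperty",
  "ReflexiveObjectProperty", "IrreflexiveObjectProperty",
  "SymmetricObjectProperty", "AsymmetricObjectProperty",
  "TransitiveObjectProperty",
  # data property axioms
  "SubDataPropertyOf", "EquivalentDataProperties", "DisjointDataProperties",
  "DataPropertyDomain", "DataPropertyRange", "FunctionalDataProperty",
  # assertions
  "SameIndividual", "DifferentIndividuals", "ClassAssertion",
  "ObjectPropertyAssertion", "NegativeObjectPropertyAssertion",
  "DataPropertyAssertion", "NegativeDataPropertyAssertion",
  # other
  "HasKey", "DatatypeDefinition"
)

AXIOM_TYPES_NON_LOGICAL <- c(
  "Declaration", "AnnotationAssertion", "SubAnnotationPropertyOf",
  "AnnotationPropertyDomain", "AnnotationPropertyRange"
)

AXIOM_TYPES <- c(AXIOM_TYPES_LOGICAL, AXIOM_TYPES_NON_LOGICAL)

# Class-expression constructs recognised inside axiom payloads.
EXPRESSION_TYPES <- c(
  "ObjectIntersectionOf", "ObjectUnionOf", "ObjectComplementOf",
  "ObjectOneOf", "ObjectSomeValuesFrom", "ObjectAllValuesFrom",
  "ObjectHasValue", "ObjectMinCardinality", "ObjectMaxCardinality",
  "ObjectExactCardinality", "DataSomeValuesFrom"
)

#' The OWL feature catalog used as the richness denominator
#'
#' The richness sub-score divides the number of distinct language constructs
#' an ontology exercises by the number of constructs the language offers,
#' fixed at 39 for OWL.  The catalog enumerated here pins that denominator
#' to an explicit, auditable list: 28 axiom-type constructs plus 11
#' class-expression constructs.  A construct counts as "used" when at least
#' one axiom of that type, or one expression of that shape inside any axiom
#' payload, occurs in the ontology.
#'
#' @return Character vector of exactly 39 OWL 2 construct identifiers, in a
#'   fixed order.
#' @seealso [survey_features()], [richness()]
#' @export
#' @examples
#' length(owl_feature_catalog())  # 39
owl_feature_catalog <- function() {
  axiom_features <- setdiff(
    AXIOM_TYPES_LOGICAL,
    c("NegativeObjectPropertyAssertion", "NegativeDataPropertyAssertion",
      "HasKey", "DatatypeDefinition")
  )
  c(axiom_features, EXPRESSION_TYPES)
}

stopifnot(length(owl_feature_catalog()) == 39L)

#' Logical axiom types the verbalizer can render
#'
#' The verbalizer carries one English template per supported logical axiom
#' type; the supported set is fixed at 25 types spanning class axioms,
#' object- and data-property axioms, property characteristics and
#' assertions.  Logical axioms outside this set are counted as unsupported
#' rather than silently dropped, so statement accounting always reconciles
#' with the logical-axiom census.
#'
#' @return Character vector of exactly 25 axiom-type tags, in a fixed order.
#' @seealso [verbalize_axiom()], [verbalize_ontology()]
#' @export
#' @examples
#' length(supported_axiom_types())  # 25
#' "SubClassOf" %in% supported_axiom_types()
supported_axiom_types <- function() {
  setdiff(
    AXIOM_TYPES_LOGICAL,
    c("DisjointUnion", "DisjointObjectProperties", "EquivalentDataProperties",
      "DisjointDataProperties", "NegativeObjectPropertyAssertion",
      "NegativeDataPropertyAssertion", "DatatypeDefinition")
  )
}

stopifnot(length(supported_axiom_types()) == 25L)
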