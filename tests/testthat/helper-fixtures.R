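# Shared fixtures: tiny Turtle ontologies written on the fly, the demo
# lexicon, and a fully saturated model exercising every cataloged
# construct.

TTL_PREFIXES <- c(
  "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
  "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
  "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
  "@prefix ex: <http://ex.org/onto#> ."
)

write_ttl <- function(lines, prefixes = TTL_PREFIXES) {
  path <- tempfile(fileext = ".ttl")
  writeLines(c(prefixes, lines), path)
  path
}

load_ttl <- function(lines) load_ontology(write_ttl(lines))

demo_lexicon <- function() {
  fixture_lexicon(c(heart = 3, attack = 5, disease = 2, organ = 4))
}

synth_lexicon <- function() fixture_lexicon(ontoqc:::SYNTH_VOCABULARY)

# One axiom per cataloged construct: the 28 axiom-type features plus a
# SubClassOf carrying each of the 11 expression features.
saturated_model <- function() {
  ax <- ontoqc:::axiom
  lit <- ontoqc:::owl_literal
  e <- function(x) paste0("http://ex.org/sat#", x)
  m <- ontoqc:::new_ontology_model()
  m$ontology_iri <- "http://ex.org/sat"
  m$entities$classes <- e(c("C1", "C2", "C3"))
  m$entities$individuals <- e(c("i1", "i2"))
  m$entities$object_properties <- e(c("p", "q"))
  m$entities$data_properties <- e(c("d", "d2"))
  axs <- list(
    ax("SubClassOf", sub = e("C1"), sup = e("C2")),
    ax("EquivalentClasses", classes = list(e("C1"), e("C3"))),
    ax("DisjointClasses", classes = list(e("C2"), e("C3"))),
    ax("DisjointUnion", class = e("C1"),
       disjuncts = list(e("C2"), e("C3"))),
    ax("SubObjectPropertyOf", sub = e("p"), sup = e("q")),
    ax("EquivalentObjectProperties", properties = list(e("p"), e("q"))),
    ax("DisjointObjectProperties", properties = list(e("p"), e("q"))),
    ax("InverseObjectProperties", first = e("p"), second = e("q")),
    ax("ObjectPropertyDomain", property = e("p"), ce = e("C1")),
    ax("ObjectPropertyRange", property = e("p"), ce = e("C2")),
    ax("FunctionalObjectProperty", property = e("p")),
    ax("InverseFunctionalObjectProperty", property = e("p")),
    ax("ReflexiveObjectProperty", property = e("p")),
    ax("IrreflexiveObjectProperty", property = e("q")),
    ax("SymmetricObjectProperty", property = e("p")),
    ax("AsymmetricObjectProperty", property = e("q")),
    ax("TransitiveObjectProperty", property = e("p")),
    ax("SubDataPropertyOf", sub = e("d"), sup = e("d2")),
    ax("EquivalentDataProperties", properties = list(e("d"), e("d2"))),
    ax("DisjointDataProperties", properties = list(e("d"), e("d2"))),
    ax("DataPropertyDomain", property = e("d"), ce = e("C1")),
    ax("DataPropertyRange", property = e("d"),
       range = "http://www.w3.org/2001/XMLSchema#string"),
    ax("FunctionalDataProperty", property = e("d")),
    ax("SameIndividual", individuals = list(e("i1"), e("i2"))),
    ax("DifferentIndividuals", individuals = list(e("i1"), e("i2"))),
    ax("ClassAssertion", ce = e("C1"), individual = e("i1")),
    ax("ObjectPropertyAssertion", property = e("p"), subject = e("i1"),
       object = e("i2")),
    ax("DataPropertyAssertion", property = e("d"), subject = e("i1"),
       value = lit("42"))
  )
  exprs <- list(
    list(type = "ObjectIntersectionOf", operands = list(e("C1"), e("C2"))),
    list(type = "ObjectUnionOf", operands = list(e("C1"), e("C2"))),
    list(type = "ObjectComplementOf", operand = e("C1")),
    list(type = "ObjectOneOf", individuals = list(e("i1"), e("i2"))),
    list(type = "ObjectSomeValuesFrom", property = e("p"), filler = e("C1")),
    list(type = "ObjectAllValuesFrom", property = e("p"), filler = e("C2")),
    list(type = "ObjectHasValue", property = e("p"), individual = e("i1")),
    list(type = "ObjectMinCardinality", n = 1L, property = e("q")),
    list(type = "ObjectMaxCardinality", n = 2L, property = e("q")),
    list(type = "ObjectExactCardinality", n = 1L, property = e("q")),
    list(type = "DataSomeValuesFrom", property = e("d"),
         range = "http://www.w3.org/2001/XMLSchema#string")
  )
  for (k in seq_along(exprs)) {
    axs[[length(axs) + 1L]] <- ax("SubClassOf", sub = e("C3"),
                                  sup = exprs[[k]])
  }
  m$axioms <- axs
  m
}
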