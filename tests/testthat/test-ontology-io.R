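# Loading, censuses, feature survey, violations, label extraction.

test_that("a minimal one-class ontology parses to one declaration", {
  m <- load_ttl("ex:A a owl:Class .")
  expect_s3_class(m, "ontology_model")
  expect_equal(census_elements(m)$n_classes, 1L)
  ax <- census_axioms(m)
  expect_equal(ax$n_logical, 0L)
  expect_equal(ax$n_non_logical, 1L)
})

test_that("loading the same file twice yields identical models", {
  path <- write_ttl(c(
    "ex:A a owl:Class ; rdfs:label \"Heart\" .",
    "ex:B a owl:Class .",
    "ex:A rdfs:subClassOf ex:B ."))
  m1 <- load_ontology(path)
  m2 <- load_ontology(path)
  expect_identical(m1, m2)
})

test_that("missing files and broken syntax raise typed errors", {
  expect_error(load_ontology(tempfile()), class = "ontoqc_io_error")
  bad <- tempfile(fileext = ".ttl")
  writeLines("ex:A a <unclosed", bad)
  expect_error(load_ontology(bad), class = "ontoqc_format_error")
})

test_that("axiom census follows the logical/non-logical classification", {
  m <- load_ttl(c(
    "ex:A a owl:Class .",                       # declaration
    "ex:B a owl:Class .",                       # declaration
    "ex:A rdfs:label \"Heart\" .",              # annotation assertion
    "ex:A rdfs:subClassOf ex:B .",
    "ex:B rdfs:subClassOf owl:Thing .",
    "ex:A owl:disjointWith ex:B ."))
  ax <- census_axioms(m)
  expect_equal(ax$n_logical, 3L)
  expect_equal(ax$n_non_logical, 3L)
  expect_equal(ax$n_total, 6L)
  expect_true(ax$n_total >= ax$n_logical)
})

test_that("element census sums the four declared kinds", {
  m <- load_ttl(c(
    sprintf("ex:C%d a owl:Class .", 1:5),
    sprintf("ex:i%d a owl:NamedIndividual .", 1:2),
    "ex:p a owl:ObjectProperty .",
    "ex:d a owl:DatatypeProperty ."))
  el <- census_elements(m)
  expect_equal(el$n_classes, 5L)
  expect_equal(el$n_individuals, 2L)
  expect_equal(el$n_object_properties, 1L)
  expect_equal(el$n_data_properties, 1L)
  expect_equal(el$n_elements, 9L)
})

test_that("feature survey reports the exercised subset of the catalog", {
  empty <- load_ttl(character())
  expect_length(survey_features(empty)$used, 0L)

  two <- load_ttl(c(
    "ex:A a owl:Class .", "ex:B a owl:Class .",
    "ex:A rdfs:subClassOf ex:B .",
    "ex:i a owl:NamedIndividual , ex:A ."))
  expect_setequal(survey_features(two)$used,
                  c("SubClassOf", "ClassAssertion"))

  sat <- saturated_model()
  inv <- survey_features(sat)
  expect_length(inv$catalog, 39L)
  expect_length(inv$used, 39L)
})

test_that("feature survey is invariant under axiom re-ordering", {
  lines <- c(
    "ex:A a owl:Class .", "ex:B a owl:Class .",
    "ex:A rdfs:subClassOf ex:B .",
    "ex:A owl:disjointWith ex:B .")
  m1 <- load_ttl(lines)
  m2 <- load_ttl(rev(lines))
  expect_setequal(survey_features(m1)$used, survey_features(m2)$used)
})

test_that("DL violation count flags punning and stays 0 on clean input", {
  expect_equal(count_dl_violations(load_ttl(character())), 0L)
  clean <- load_ttl(c("ex:A a owl:Class .", "ex:B a owl:Class .",
                      "ex:A rdfs:subClassOf ex:B ."))
  expect_equal(count_dl_violations(clean), 0L)
  punned <- load_ttl(c("ex:A a owl:Class .", "ex:A a rdfs:Datatype ."))
  expect_gte(count_dl_violations(punned), 1L)
})

test_that("label extraction honors labels, fallbacks and language preference", {
  m <- load_ttl(c(
    "ex:MI a owl:Class ; rdfs:label \"Heart Attack\" .",
    "ex:MyocardialInfarction a owl:Class .",
    "ex:X a owl:Class ; rdfs:label \"coeur\"@fr , \"heart\"@en ."))
  lab <- extract_labels(m, language_preference = c("", "en"))
  lookup <- stats::setNames(lab$raw_label, lab$entity_iri)
  expect_equal(lookup[["http://ex.org/onto#MI"]], "Heart Attack")
  expect_equal(lookup[["http://ex.org/onto#MyocardialInfarction"]],
               "MyocardialInfarction")
  expect_equal(lookup[["http://ex.org/onto#X"]], "heart")
})

test_that("imports are left alone by default and merged on request", {
  b <- write_ttl(c("@prefix exb: <http://ex.org/B#> .",
                   "<http://ex.org/B> a owl:Ontology .",
                   "exb:B1 a owl:Class .", "exb:B2 a owl:Class .",
                   "exb:B1 rdfs:subClassOf exb:B2 ."))
  a <- write_ttl(c(
    "<http://ex.org/A> a owl:Ontology ; owl:imports <http://ex.org/B> .",
    "ex:A1 a owl:Class .", "ex:A2 a owl:Class .",
    "ex:A1 rdfs:subClassOf ex:A2 ."))
  ma <- load_ontology(a)

  expect_warning(local_only <- merge_imports(ma, follow = FALSE),
                 class = "ontoqc_unresolved_imports")
  expect_equal(census_axioms(local_only)$n_logical, 1L)

  merged <- merge_imports(ma, follow = TRUE,
                          import_map = c("http://ex.org/B" = b))
  expect_equal(census_axioms(merged)$n_logical, 2L)
  expect_equal(census_elements(merged)$n_classes, 4L)

  # idempotent, and a no-import model is returned unchanged
  expect_identical(merge_imports(merged, follow = TRUE), merged)
  no_imp <- load_ttl("ex:A a owl:Class .")
  expect_identical(merge_imports(no_imp, follow = TRUE), no_imp)

  expect_error(merge_imports(ma, follow = TRUE),
               class = "ontoqc_resolution_error")
})

test_that("RDF/XML and Turtle serializations of one ontology agree", {
  xml <- tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "  xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "  xmlns:owl=\"http://www.w3.org/2002/07/owl#\">",
    "  <owl:Ontology rdf:about=\"http://ex.org/onto\"/>",
    "  <owl:Class rdf:about=\"http://ex.org/onto#A\">",
    "    <rdfs:label>Heart</rdfs:label>",
    "    <rdfs:subClassOf rdf:resource=\"http://ex.org/onto#B\"/>",
    "  </owl:Class>",
    "  <owl:Class rdf:about=\"http://ex.org/onto#B\"/>",
    "</rdf:RDF>"), xml)
  ttl <- write_ttl(c(
    "<http://ex.org/onto> a owl:Ontology .",
    "ex:A a owl:Class ; rdfs:label \"Heart\" ; rdfs:subClassOf ex:B .",
    "ex:B a owl:Class ."))
  mx <- load_ontology(xml)
  mt <- load_ontology(ttl)
  expect_identical(unclass(census_axioms(mx)), unclass(census_axioms(mt)))
  expect_identical(mx$entities, mt$entities)
  expect_setequal(vapply(mx$axioms, ontoqc:::axiom_functional, ""),
                  vapply(mt$axioms, ontoqc:::axiom_functional, ""))
})
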