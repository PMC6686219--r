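# Axiom-to-English templates, statement accounting and URI hygiene.

test_that("the supported-type enumeration is fixed, deterministic and complete", {
  types <- supported_axiom_types()
  expect_length(types, 25L)
  expect_length(unique(types), 25L)
  expect_true(all(c("SubClassOf", "ObjectPropertyDomain") %in% types))
  expect_identical(types, supported_axiom_types())
})

test_that("entity rendering prefers labels and humanizes fragments", {
  lm <- c("http://ex.org/onto#MI" = "myocardial infarction")
  expect_equal(render_entity("http://ex.org/onto#MI", lm),
               "myocardial infarction")
  expect_equal(render_entity("http://ex.org/onto#HeartAttack"),
               "heart attack")
  expect_equal(render_entity("http://ex.org/rel/has_part"), "has part")
})

test_that("core templates render the expected sentences", {
  ax <- ontoqc:::axiom
  lm <- c("http://x/MI" = "myocardial infarction",
          "http://x/HD" = "heart disease",
          "http://x/hasAgent" = "has agent",
          "http://x/Event" = "event")
  sub <- verbalize_axiom(ax("SubClassOf", sub = "http://x/MI",
                            sup = "http://x/HD"), lm)
  expect_equal(sub$sentence, "Every myocardial infarction is a heart disease.")
  dom <- verbalize_axiom(ax("ObjectPropertyDomain",
                            property = "http://x/hasAgent",
                            ce = "http://x/Event"), lm)
  expect_equal(dom$sentence, "Anything that has agent something is an event.")
  # nested class expression
  nested <- verbalize_axiom(ax("SubClassOf", sub = "http://x/MI",
    sup = list(type = "ObjectSomeValuesFrom", property = "http://x/hasAgent",
               filler = "http://x/Event")), lm)
  expect_match(nested$sentence,
               "Every myocardial infarction is something that has agent an event")
})

test_that("unsupported logical axiom types yield the unsupported marker", {
  ax <- ontoqc:::axiom
  expect_null(verbalize_axiom(ax("DisjointUnion", class = "http://x/A",
                                 disjuncts = list("http://x/B", "http://x/C"))))
})

test_that("statement ids are stable and sentences are pure functions", {
  ax <- ontoqc:::axiom("SubClassOf", sub = "http://x/A", sup = "http://x/B")
  s1 <- verbalize_axiom(ax)
  s2 <- verbalize_axiom(ax)
  expect_identical(s1, s2)
  other <- ontoqc:::axiom("SubClassOf", sub = "http://x/B", sup = "http://x/A")
  expect_false(verbalize_axiom(other)$statement_id == s1$statement_id)
})

test_that("statement accounting reconciles with the logical census", {
  empty <- load_ttl(character())
  s0 <- verbalize_ontology(empty)
  expect_equal(nrow(s0$statements), 0L)
  expect_equal(s0$n_unsupported, 0L)

  m <- load_ttl(c(
    sprintf("ex:C%d a owl:Class .", 1:11),
    sprintf("ex:C%d rdfs:subClassOf ex:C%d .", 1:10, 2:11)))
  s <- verbalize_ontology(m)
  expect_equal(nrow(s$statements), 10L)
  expect_equal(s$n_unsupported, 0L)

  for (seed in c(2, 9, 23)) {
    spec <- synth_spec(seed = seed)
    path <- tempfile(fileext = ".ttl")
    generate_ontology(spec, path)
    model <- load_ontology(path)
    ss <- verbalize_ontology(model)
    expect_equal(nrow(ss$statements) + ss$n_unsupported,
                 census_axioms(model)$n_logical)
  }
})

test_that("no emitted sentence contains a raw URI", {
  for (seed in c(4, 17)) {
    spec <- synth_spec(seed = seed,
                       features = c("ObjectSomeValuesFrom", "ObjectUnionOf"))
    path <- tempfile(fileext = ".ttl")
    generate_ontology(spec, path)
    ss <- verbalize_ontology(load_ontology(path))
    expect_false(any(grepl("http://|https://", ss$statements$sentence)))
  }
})

test_that("statements come out sorted by statement id", {
  spec <- synth_spec(seed = 12)
  path <- tempfile(fileext = ".ttl")
  generate_ontology(spec, path)
  ss <- verbalize_ontology(load_ontology(path))
  expect_identical(ss$statements$statement_id,
                   sort(ss$statements$statement_id))
})
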