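# Session orchestration: scorecards, snapshots, reports, config files.

demo_config <- function(path, ...) {
  score_config(
    ontology = path,
    baseline_average = 500,
    lexicon = synth_lexicon(),
    ...
  )
}

synth_path <- function(seed = 3L, ...) {
  path <- tempfile(fileext = ".ttl")
  generate_ontology(synth_spec(seed = seed, ...), path)
  path
}

test_that("a scorecard equals hand-chained stage calls", {
  path <- synth_path(seed = 3L)
  card <- build_scorecard(demo_config(path))

  model <- load_ontology(path)
  ax <- census_axioms(model)
  el <- census_elements(model)
  inv <- survey_features(model)
  v <- count_dl_violations(model)
  recs <- label_records(model)
  tok <- census_tokens(recs)
  st <- sense_stats(synth_lexicon(), tok)

  expect_equal(card$scores$SL, lawfulness(ax, v, "classic"))
  expect_equal(card$scores$SR, richness(inv))
  expect_equal(card$scores$EI, interpretability(st, "classic"))
  expect_equal(card$scores$EA, clarity(st))
  expect_equal(card$scores$EC, consistency(tok))
  expect_equal(card$scores$PO, comprehensiveness(el, 500))
  expect_equal(card$scores$S, mean(c(card$scores$SL, card$scores$SR)))
  expect_equal(card$scores$E,
               mean(c(card$scores$EI, card$scores$EC, card$scores$EA)))
  # PU and PR absent: pragmatic collapses to PO
  expect_equal(card$scores$P, card$scores$PO)
  expect_equal(card$scores$Q,
               mean(c(card$scores$S, card$scores$E, card$scores$P)))
})

test_that("social is excluded by default and Q spans three aspects", {
  card <- build_scorecard(demo_config(synth_path(4L)))
  expect_null(card$scores$O)
  expect_equal(card$excluded_aspects, "social")
  expect_equal(unname(card$weights$aspect),
               c(1 / 3, 1 / 3, 1 / 3, 0))
})

test_that("manual social inputs activate the social aspect", {
  card <- build_scorecard(demo_config(
    synth_path(5L), excluded_aspects = character(),
    authority = 0.8, history = 0.6))
  expect_equal(card$scores$O, 0.7)
  expect_equal(unname(card$weights$aspect), rep(0.25, 4))
})

test_that("configuration errors are raised before any computation", {
  expect_error(
    score_config(ontology = "x.ttl", baseline_average = NULL,
                 lexicon = synth_lexicon()),
    class = "ontoqc_configuration_error")
  expect_error(
    score_config(ontology = "x.ttl", baseline_average = 500,
                 excluded_aspects = character()),
    class = "ontoqc_configuration_error")  # social active, no manual input
  expect_error(
    score_config(ontology = "x.ttl", baseline_average = 500,
                 relevancy = 1.2),
    class = "ontoqc_parameter_error")
  cfg <- demo_config(tempfile(fileext = ".ttl"))
  expect_error(build_scorecard(cfg), class = "ontoqc_io_error")
})

test_that("snapshots round-trip scores to full precision", {
  card <- build_scorecard(demo_config(synth_path(7L)))
  path <- tempfile(fileext = ".json")
  save_snapshot(card, path)
  back <- load_snapshot(path)
  for (nm in names(card$scores)) {
    expect_equal(back$scores[[nm]], card$scores[[nm]], tolerance = 1e-12,
                 info = nm)
  }
  expect_equal(back$excluded_aspects, card$excluded_aspects)
  expect_equal(unclass(back$modes), unclass(card$modes))
})

test_that("snapshot loading rejects truncation and version drift", {
  card <- build_scorecard(demo_config(synth_path(7L)))
  path <- tempfile(fileext = ".json")
  save_snapshot(card, path)
  txt <- readLines(path, warn = FALSE)
  trunc <- tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 50), trunc)
  expect_error(load_snapshot(trunc), class = "ontoqc_parse_error")

  drift <- tempfile(fileext = ".json")
  writeLines(sub("\"schema_version\":1", "\"schema_version\":99",
                 paste(txt, collapse = "")), drift)
  expect_error(load_snapshot(drift), class = "ontoqc_version_error")
  expect_error(load_snapshot(tempfile()), class = "ontoqc_io_error")
})

test_that("two snapshots of one session differ only in timestamp", {
  cfg <- demo_config(synth_path(9L))
  c1 <- build_scorecard(cfg)
  c2 <- build_scorecard(cfg)
  c1$generated_at <- c2$generated_at <- "T"
  expect_identical(c1, c2)
})

test_that("reports flag over-baseline comprehensiveness and exclusions", {
  path <- synth_path(3L)
  card <- build_scorecard(score_config(
    ontology = path, baseline_average = 2,  # tiny baseline pushes PO > 1
    lexicon = synth_lexicon()))
  txt <- render_report(card, "text")
  expect_true(any(grepl("over baseline", txt)))
  expect_true(any(grepl("excluded aspects: social", txt)))

  js <- jsonlite::fromJSON(render_report(card, "json"))
  expect_true(js$flags$over_baseline)
  expect_equal(js$scores$Q, card$scores$Q, tolerance = 1e-12)
})

test_that("YAML configs reload into working sessions", {
  onto <- synth_path(11L)
  lex_csv <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(token = names(ontoqc:::SYNTH_VOCABULARY),
               sense_count = unname(ontoqc:::SYNTH_VOCABULARY)),
    lex_csv, row.names = FALSE)
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    ontology = onto,
    baseline_average = 500,
    excluded_aspects = "social",
    lexicon = list(backend = "fixture", path = lex_csv),
    weights = list(aspect = list(syntactic = 0.15, semantic = 0.51,
                                 pragmatic = 0.33, social = 0),
                   auto_normalize = FALSE)
  ), cfg_path)
  cfg <- read_score_config(cfg_path)
  card <- build_scorecard(cfg)
  expect_equal(unname(card$weights$aspect), c(0.15, 0.51, 0.33, 0))
  direct <- build_scorecard(demo_config(
    onto, weights = quality_weights(
      aspect = c(syntactic = 0.15, semantic = 0.51, pragmatic = 0.33,
                 social = 0), auto_normalize = FALSE)))
  expect_equal(card$scores$Q, direct$scores$Q, tolerance = 1e-12)
})
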