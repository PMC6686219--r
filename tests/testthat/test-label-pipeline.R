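# Normalization rules, tokenization and corpus-wide token tallies.

test_that("normalization applies the documented rules", {
  expect_equal(normalize_label("HeartAttack"), "heart attack")
  expect_equal(normalize_label("the_Heart(organ)"), "heart organ")
  expect_equal(normalize_label("Blood-Vessel_Wall"), "blood vessel wall")
  off <- parse_options(split_camel_case = FALSE, remove_determiners = FALSE,
                       strip_brackets = FALSE, replace_underscores = FALSE,
                       replace_dashes = FALSE, lowercase = FALSE)
  expect_equal(normalize_label("Heart-Attack", off), "Heart-Attack")
})

test_that("bracket stripping keeps enclosed text unless told to drop it", {
  expect_equal(normalize_label("heart (organ)"), "heart organ")
  drop <- parse_options(drop_bracketed = TRUE)
  expect_equal(normalize_label("heart (organ)", drop), "heart")
})

test_that("labels that normalize to nothing yield the sentinel", {
  sentinel <- normalize_label("the")
  expect_equal(sentinel, ontoqc:::EMPTY_AFTER_PROCESSING)
  expect_equal(tokenize_label(sentinel), character())
})

test_that("normalization is idempotent under default options", {
  raws <- c("HeartAttack", "the_Heart(organ)", "BLOOD pressure",
            "an-acute_MyocardialInfarction", "a", "x(y)[z]{w}",
            "CamelCaseABCDef", "already normal text")
  for (raw in raws) {
    once <- normalize_label(raw)
    expect_equal(normalize_label(once), once, info = raw)
  }
})

test_that("tokenization splits on whitespace and drops empties", {
  expect_equal(tokenize_label("heart attack"), c("heart", "attack"))
  expect_equal(tokenize_label("heart"), "heart")
  expect_equal(tokenize_label(normalize_label("  ")), character())
})

test_that("token census matches the definitional example", {
  cen <- census_tokens(list(c("heart", "attack"), c("heart", "disease")))
  expect_equal(cen$occurrences, 4L)
  expect_equal(cen$t, 3L)
  expect_equal(cen$d, 1L)
  expect_equal(sum(cen$per_token_counts), cen$occurrences)

  distinct <- census_tokens(list(c("a1", "b2"), c("c3")))
  expect_equal(distinct$d, 0L)

  empty <- census_tokens(list())
  expect_equal(empty$occurrences, 0L)
  expect_equal(empty$t, 0L)
})

test_that("token census equals a brute-force recount on random labels", {
  set.seed(42)
  vocab <- sprintf("word%02d", 1:10)
  labels <- replicate(100, sample(vocab, sample(1:3, 1), replace = TRUE),
                      simplify = FALSE)
  cen <- census_tokens(labels)
  # independent straight-line recount over the flattened token list
  flat <- unlist(labels)
  expect_equal(cen$occurrences, length(flat))
  expect_equal(cen$t, length(unique(flat)))
  expect_equal(cen$d, length(flat) - length(unique(flat)))
  for (tk in unique(flat)) {
    expect_equal(cen$per_token_counts[[tk]], sum(flat == tk))
  }
})

test_that("token census is invariant under record permutation and d is bounded", {
  set.seed(7)
  labels <- replicate(30, sample(letters[1:6], 2, replace = TRUE),
                      simplify = FALSE)
  c1 <- census_tokens(labels)
  c2 <- census_tokens(labels[sample(seq_along(labels))])
  expect_equal(c1$occurrences, c2$occurrences)
  expect_equal(c1$t, c2$t)
  expect_equal(c1$d, c2$d)
  expect_equal(c1$per_token_counts[sort(names(c1$per_token_counts))],
               c2$per_token_counts[sort(names(c2$per_token_counts))])
  expect_true(c1$d >= 0 && c1$d < c1$occurrences)
})

test_that("label records join extraction, normalization and tokenization", {
  m <- load_ttl(c(
    "ex:MI a owl:Class ; rdfs:label \"HeartAttack\" .",
    "ex:BloodVessel a owl:Class ."))
  rec <- label_records(m)
  by_iri <- stats::setNames(rec$processed_label, rec$entity_iri)
  expect_equal(by_iri[["http://ex.org/onto#MI"]], "heart attack")
  expect_equal(by_iri[["http://ex.org/onto#BloodVessel"]], "blood vessel")
  expect_equal(rec$tokens[[match("http://ex.org/onto#MI", rec$entity_iri)]],
               c("heart", "attack"))
})
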