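# Review CSV round-trip and accuracy inputs.

make_statements <- function(n = 10L) {
  m <- load_ttl(c(
    sprintf("ex:C%d a owl:Class .", seq_len(n + 1L)),
    sprintf("ex:C%d rdfs:subClassOf ex:C%d .", seq_len(n), seq_len(n) + 1L)))
  verbalize_ontology(m)
}

fill_review <- function(stmts, verdicts, path = tempfile(fileext = ".csv")) {
  export_statements(stmts, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$verdict <- verdicts
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("export writes the byte-exact schema and empty sets export too", {
  stmts <- make_statements(3L)
  path <- tempfile(fileext = ".csv")
  export_statements(stmts, path)
  lines <- readLines(path)
  expect_equal(lines[[1L]],
               "\"statement_id\",\"axiom_type\",\"sentence\",\"verdict\",\"note\"")
  expect_length(lines, 4L)

  empty <- verbalize_ontology(load_ttl(character()))
  p2 <- tempfile(fileext = ".csv")
  export_statements(empty, p2)
  expect_length(readLines(p2), 1L)
})

test_that("unedited export imports as fully unjudged with zero-true accuracy", {
  stmts <- make_statements(4L)
  path <- tempfile(fileext = ".csv")
  export_statements(stmts, path)
  expect_warning(rs <- import_judgments(path, "r1", stmts),
                 class = "ontoqc_partial_review")
  expect_true(all(rs$judgments$verdict == "unjudged"))
  expect_equal(unname(rs$coverage), 0)
  expect_error(accuracy_from_review(rs, 4L),
               class = "ontoqc_undefined_score")
})

test_that("verdicts parse case-insensitively and coverage is reported", {
  stmts <- make_statements(10L)
  path <- fill_review(stmts, c(rep("TRUE", 4), rep("true", 4),
                               rep("False", 2)))
  rs <- import_judgments(path, "r1", stmts)
  expect_equal(sum(rs$judgments$verdict == "true"), 8L)
  expect_equal(sum(rs$judgments$verdict == "false"), 2L)
  expect_equal(unname(rs$coverage), 1)

  half <- fill_review(stmts, c(rep("true", 5), rep("", 5)))
  expect_warning(rs2 <- import_judgments(half, "r2", stmts),
                 class = "ontoqc_partial_review")
  expect_equal(unname(rs2$coverage), 0.5)
})

test_that("malformed reviews are rejected with pointed errors", {
  stmts <- make_statements(3L)
  bad_verdict <- fill_review(stmts, c("true", "maybe", "false"))
  expect_error(import_judgments(bad_verdict, "r1", stmts),
               class = "ontoqc_parse_error")

  path <- tempfile(fileext = ".csv")
  export_statements(stmts, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$statement_id[2] <- "deadbeefdeadbeef"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(import_judgments(path, "r1", stmts),
               class = "ontoqc_data_error")

  dup <- utils::read.csv(fill_review(stmts, rep("true", 3)),
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(rbind(dup, dup[1, ]), p3, row.names = FALSE)
  expect_error(import_judgments(p3, "r1", stmts),
               class = "ontoqc_data_error")

  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), p4, row.names = FALSE)
  expect_error(import_judgments(p4, "r1", stmts),
               class = "ontoqc_parse_error")
})

test_that("import is insensitive to row order", {
  stmts <- make_statements(6L)
  path <- fill_review(stmts, c(rep("true", 3), rep("false", 3)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  shuffled <- tempfile(fileext = ".csv")
  utils::write.csv(df[rev(seq_len(nrow(df))), ], shuffled, row.names = FALSE)
  r1 <- import_judgments(path, "r", stmts)
  r2 <- import_judgments(shuffled, "r", stmts)
  a1 <- accuracy_from_review(r1, 6L)
  a2 <- accuracy_from_review(r2, 6L)
  expect_equal(a1$PU, a2$PU)
})

test_that("review accuracy reproduces the hand-computed examples", {
  stmts <- make_statements(10L)
  r1 <- import_judgments(fill_review(stmts, c(rep("true", 8),
                                              rep("false", 2))), "r1", stmts)
  r2 <- import_judgments(fill_review(stmts, c(rep("true", 6),
                                              rep("false", 4))), "r2", stmts)
  acc <- accuracy_from_review(combine_reviews(r1, r2), 10L)
  expect_equal(acc$PU, 0.7)
  expect_equal(sort(acc$per_reviewer$true_n), c(6L, 8L))
})

test_that("the denominator policy splits as documented on partial reviews", {
  stmts <- make_statements(20L)
  path <- fill_review(stmts, c(rep("true", 5), rep("false", 5), rep("", 10)))
  suppressWarnings(rs <- import_judgments(path, "r1", stmts))
  suppressWarnings({
    all_den <- accuracy_from_review(rs, 20L, denominator = "all")
    judged_den <- accuracy_from_review(rs, 20L, denominator = "judged")
  })
  expect_equal(all_den$PU, 0.25)
  expect_equal(judged_den$PU, 0.5)
  expect_lte(all_den$PU, judged_den$PU)
})
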