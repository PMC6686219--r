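# Expert-review round-trip: export verbalized statements as a CSV grid,
# import per-reviewer verdicts, compute the accuracy inputs.  The email /
# invite-link workflow is replaced by one file per reviewer keyed by
# reviewer_id; the data flow is unchanged.

REVIEW_HEADER <- c("statement_id", "axiom_type", "sentence", "verdict", "note")

#' Export a statement set for review
#'
#' Writes the grid a reviewer fills in: one row per statement with blank
#' `verdict` and `note` columns.  The header is byte-exact
#' (`statement_id,axiom_type,sentence,verdict,note`) so files re-import
#' without loss.
#'
#' @param set A `statement_set` from [verbalize_ontology()].
#' @param destination Output CSV path.
#' @return The path, invisibly.
#' @export
export_statements <- function(set, destination) {
  stopifnot(inherits(set, "statement_set"))
  df <- set$statements[, c("statement_id", "axiom_type", "sentence")]
  df$verdict <- rep("", nrow(df))
  df$note <- rep("", nrow(df))
  tryCatch(
    utils::write.csv(df, destination, row.names = FALSE, quote = TRUE),
    error = function(e) abort_ontoqc(
      sprintf("cannot write review file '%s': %s", destination,
              conditionMessage(e)), "ontoqc_io_error"))
  invisible(destination)
}

#' Import one reviewer's verdicts
#'
#' Parses the verdict column case-insensitively (`true` / `false` / blank =
#' unjudged).  Unknown statement ids and duplicate rows are rejected; any
#' other verdict string is a parse error naming the row.  Import is
#' insensitive to row order.
#'
#' @param file Filled-in review CSV.
#' @param reviewer_id Identifier for this reviewer.
#' @param statement_set The `statement_set` the file was exported from.
#' @return List of class `review_set` with a `judgments` data frame
#'   (`reviewer_id`, `statement_id`, `verdict`, `note`), `reviewers`, and
#'   per-reviewer `coverage`.
#' @export
import_judgments <- function(file, reviewer_id, statement_set) {
  stopifnot(inherits(statement_set, "statement_set"))
  if (!file.exists(file)) {
    abort_ontoqc(sprintf("review file not found: %s", file),
                 "ontoqc_io_error")
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), REVIEW_HEADER)) {
    abort_ontoqc(sprintf(
      "review file '%s' does not match the export schema (%s)", file,
      paste(REVIEW_HEADER, collapse = ",")), "ontoqc_parse_error")
  }
  known <- statement_set$statements$statement_id
  unknown <- setdiff(df$statement_id, known)
  if (length(unknown)) {
    abort_ontoqc(paste0("unknown statement ids: ",
                        paste(unknown, collapse = ", ")),
                 "ontoqc_data_error")
  }
  if (anyDuplicated(df$statement_id)) {
    dup <- df$statement_id[duplicated(df$statement_id)]
    abort_ontoqc(paste0("duplicate statement ids in one review file: ",
                        paste(unique(dup), collapse = ", ")),
                 "ontoqc_data_error")
  }
  verdict_raw <- trimws(tolower(df$verdict))
  bad <- which(!verdict_raw %in% c("true", "false", ""))
  if (length(bad)) {
    abort_ontoqc(sprintf(
      "unparseable verdict '%s' at data row %d (expected true/false/blank)",
      df$verdict[[bad[[1L]]]], bad[[1L]]), "ontoqc_parse_error")
  }
  verdict <- ifelse(verdict_raw == "", "unjudged", verdict_raw)
  judgments <- data.frame(
    reviewer_id = rep(reviewer_id, nrow(df)),
    statement_id = df$statement_id,
    verdict = verdict,
    note = df$note,
    stringsAsFactors = FALSE)
  coverage <- if (length(known)) {
    sum(verdict != "unjudged" & df$statement_id %in% known) / length(known)
  } else 0
  if (coverage < 1 && length(known)) {
    warn_ontoqc(sprintf("reviewer '%s' judged %.0f%% of statements",
                        reviewer_id, 100 * coverage),
                "ontoqc_partial_review")
  }
  structure(list(
    judgments = judgments,
    reviewers = reviewer_id,
    coverage = stats::setNames(coverage, reviewer_id)
  ), class = "review_set")
}

#' Combine per-reviewer review sets
#'
#' @param ... `review_set` objects (one per reviewer).
#' @return A merged `review_set`.
#' @export
combine_reviews <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "review_set")))
  structure(list(
    judgments = do.call(rbind, lapply(sets, `[[`, "judgments")),
    reviewers = unlist(lapply(sets, `[[`, "reviewers")),
    coverage = do.call(c, lapply(sets, `[[`, "coverage"))
  ), class = "review_set")
}

#' Accuracy from a review set
#'
#' Counts each reviewer's true verdicts and delegates to [accuracy()].
#' Under the default denominator every logical axiom counts, so unjudged
#' statements count against accuracy (with a warning); the `"judged"`
#' denominator divides by each reviewer's judged count instead.
#'
#' @param review A `review_set`.
#' @param n_logical Logical-axiom count of the ontology under review.
#' @param denominator `"all"` (default) or `"judged"`.
#' @return List with `PU` (the averaged score) and `per_reviewer` (data
#'   frame of true counts, judged counts and per-reviewer fractions).
#' @export
accuracy_from_review <- function(review, n_logical,
                                 denominator = c("all", "judged")) {
  stopifnot(inherits(review, "review_set"))
  denominator <- match.arg(denominator)
  j <- review$judgments
  reviewers <- unique(j$reviewer_id)
  if (length(reviewers) == 0L || all(j$verdict == "unjudged")) {
    abort_ontoqc("accuracy undefined: no reviewer judged any statement",
                 "ontoqc_undefined_score")
  }
  true_n <- vapply(reviewers, function(r) {
    sum(j$reviewer_id == r & j$verdict == "true")
  }, 0L)
  judged_n <- vapply(reviewers, function(r) {
    sum(j$reviewer_id == r & j$verdict != "unjudged")
  }, 0L)
  if (denominator == "all") {
    if (any(judged_n < n_logical)) {
      warn_ontoqc("unjudged statements count as not-true under the 'all' denominator",
                  "ontoqc_partial_review")
    }
    fractions <- true_n / n_logical
    pu <- accuracy(true_n, n_logical)
  } else {
    keep <- judged_n > 0L
    fractions <- ifelse(keep, true_n / pmax(judged_n, 1L), NA_real_)
    pu <- mean(fractions[keep])
  }
  list(
    PU = pu,
    per_reviewer = data.frame(
      reviewer_id = reviewers, true_n = true_n, judged_n = judged_n,
      fraction = fractions, stringsAsFactors = FALSE)
  )
}
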