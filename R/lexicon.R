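# Pluggable lexical database: token -> word-sense count.
#
# The contract is deterministic, case-insensitive lookup with 0 for
# out-of-vocabulary tokens.  Two backends: a fixture lexicon built from a
# plain mapping (used by the test suite, no corpus download), and a reader
# for a local WordNet database directory (WNdb index files).  Sense counts
# aggregate across all parts of speech; no lemmatization is performed.

new_lexical_db <- function(name, lookup) {
  structure(list(name = name, lookup = lookup), class = "lexical_db")
}

#' @export
print.lexical_db <- function(x, ...) {
  cat("<lexical_db>", x$name, "\n")
  invisible(x)
}

#' Fixture lexicon from an explicit word-to-senses mapping
#'
#' @param vocabulary Named numeric/integer vector or two-column data frame
#'   (`token`, `sense_count`) mapping words to non-negative sense counts.
#' @return A `lexical_db`.
#' @export
#' @examples
#' db <- fixture_lexicon(c(heart = 3, attack = 5))
#' sense_count(db, "Heart")  # 3
fixture_lexicon <- function(vocabulary) {
  if (is.data.frame(vocabulary)) {
    vocabulary <- stats::setNames(vocabulary[[2L]], vocabulary[[1L]])
  }
  counts <- as.integer(vocabulary)
  if (any(is.na(counts)) || any(counts < 0L)) {
    abort_ontoqc("sense counts must be non-negative integers",
                 "ontoqc_validation_error")
  }
  names(counts) <- tolower(names(vocabulary))
  new_lexical_db("fixture", function(token) {
    idx <- match(tolower(token), names(counts))
    if (is.na(idx)) 0L else counts[[idx]]
  })
}

#' Fixture lexicon from a CSV file
#'
#' File format: two columns, `token` and `sense_count`, with a header row.
#'
#' @param path CSV path.
#' @return A `lexical_db`.
#' @export
read_lexicon_csv <- function(path) {
  if (!file.exists(path)) {
    abort_ontoqc(sprintf("lexicon file not found: %s", path),
                 "ontoqc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixture_lexicon(stats::setNames(df$sense_count, df$token))
}

#' WordNet backend from a local database directory
#'
#' Reads the `index.noun`, `index.verb`, `index.adj` and `index.adv` files
#' of a WordNet database (WNdb) directory and sums the per-lemma synset
#' counts across parts of speech.  Multi-word collocations are not
#' consulted; tokens are looked up individually.
#'
#' @param dict_dir Directory containing the WordNet index files.
#' @return A `lexical_db`.
#' @export
wordnet_lexicon <- function(dict_dir) {
  index_files <- file.path(dict_dir, paste0("index.",
                                            c("noun", "verb", "adj", "adv")))
  if (!dir.exists(dict_dir) || !any(file.exists(index_files))) {
    abort_ontoqc(paste0(
      "no WordNet index files under '", dict_dir, "'. Point dict_dir at a ",
      "WordNet 'dict' directory, or use fixture_lexicon()/",
      "read_lexicon_csv() for a bundled lexicon."),
      "ontoqc_environment_error")
  }
  senses <- new.env(parent = emptyenv())
  for (f in index_files[file.exists(index_files)]) {
    for (line in readLines(f, warn = FALSE)) {
      if (startsWith(line, " ")) next  # license header
      fields <- strsplit(line, " ", fixed = TRUE)[[1]]
      if (length(fields) < 3L) next
      lemma <- tolower(fields[[1L]])
      synset_cnt <- suppressWarnings(as.integer(fields[[3L]]))
      if (is.na(synset_cnt)) next
      prev <- if (exists(lemma, envir = senses, inherits = FALSE)) {
        get(lemma, envir = senses)
      } else 0L
      assign(lemma, prev + synset_cnt, envir = senses)
    }
  }
  new_lexical_db(paste0("wordnet:", dict_dir), function(token) {
    key <- tolower(token)
    if (exists(key, envir = senses, inherits = FALSE)) {
      get(key, envir = senses)
    } else 0L
  })
}

#' Word-sense count for one token
#'
#' @param db A `lexical_db`.
#' @param token Non-empty token text; lookup is case-insensitive.
#' @return Non-negative integer count; 0 when out of vocabulary.
#' @export
sense_count <- function(db, token) {
  stopifnot(inherits(db, "lexical_db"), is.character(token), nzchar(token))
  as.integer(db$lookup(token))
}

#' Accumulated word-sense total for a tokenized label
#'
#' Sums per-token sense counts, with repetition, forming the accumulated
#' sense total shown next to each processed label.
#'
#' @param db A `lexical_db`.
#' @param tokens Character vector of tokens (possibly empty).
#' @return Non-negative integer.
#' @export
label_sense_total <- function(db, tokens) {
  if (length(tokens) == 0L) return(0L)
  sum(vapply(tokens, function(tk) sense_count(db, tk), 0L))
}

#' Sense statistics over the unique tokens of a corpus
#'
#' Statistics are computed over unique tokens only, so they are independent
#' of token order and occurrence multiplicity: `t_sense` counts unique
#' tokens with at least one sense, `total_senses` sums sense counts, and
#' `t_avg_sense = total_senses / t`.
#'
#' @param db A `lexical_db`.
#' @param census A `token_census` from [census_tokens()]; must have
#'   `t > 0`.
#' @return List of class `sense_stats` with `t`, `t_sense`, `total_senses`,
#'   `t_avg_sense`.
#' @export
sense_stats <- function(db, census) {
  stopifnot(inherits(census, "token_census"))
  if (census$t == 0L) {
    abort_ontoqc("sense statistics undefined: no tokens in the corpus",
                 "ontoqc_undefined_score")
  }
  uniq <- names(census$per_token_counts)
  counts <- vapply(uniq, function(tk) sense_count(db, tk), 0L)
  structure(list(
    t = census$t,
    t_sense = sum(counts > 0L),
    total_senses = sum(counts),
    t_avg_sense = sum(counts) / census$t
  ), class = "sense_stats")
}
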