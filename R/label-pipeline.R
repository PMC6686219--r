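# Label normalization and token tallies.
#
# Rules are applied in a fixed, documented order because order changes
# outcomes ("theHeart"): bracket stripping, separator replacement,
# camel-case splitting, lowercasing, determiner removal, whitespace
# collapse.

#' Parsing options for label normalization
#'
#' All flags default on, mirroring a configuration in which camel-cased
#' labels are fixed and determiners, brackets, underscores and dashes are
#' removed.
#'
#' @param split_camel_case Insert a space at lower-to-upper camel-case
#'   boundaries.
#' @param remove_determiners Drop stand-alone "a", "an", "the".
#' @param strip_brackets Remove the bracket characters `()[]{}`, keeping
#'   the enclosed text (set `drop_bracketed` to discard it instead).
#' @param replace_underscores,replace_dashes Turn `_` / `-` into spaces.
#' @param lowercase Fold to lower case.
#' @param drop_bracketed Remove bracketed segments together with their
#'   content; only meaningful with `strip_brackets`.
#' @return A list of class `parse_options`.
#' @export
parse_options <- function(split_camel_case = TRUE,
                          remove_determiners = TRUE,
                          strip_brackets = TRUE,
                          replace_underscores = TRUE,
                          replace_dashes = TRUE,
                          lowercase = TRUE,
                          drop_bracketed = FALSE) {
  structure(list(
    split_camel_case = isTRUE(split_camel_case),
    remove_determiners = isTRUE(remove_determiners),
    strip_brackets = isTRUE(strip_brackets),
    replace_underscores = isTRUE(replace_underscores),
    replace_dashes = isTRUE(replace_dashes),
    lowercase = isTRUE(lowercase),
    drop_bracketed = isTRUE(drop_bracketed)
  ), class = "parse_options")
}

EMPTY_AFTER_PROCESSING <- "<empty-after-processing>"

#' Normalize a raw label
#'
#' Applies the enabled rules in the fixed order bracket stripping,
#' underscore/dash replacement, camel-case splitting, lowercasing,
#' determiner removal, whitespace collapse.  Idempotent under the default
#' options.  A label that normalizes to nothing yields the
#' empty-after-processing sentinel, which downstream tallies exclude.
#'
#' @param raw Raw label text.
#' @param options A [parse_options()] object.
#' @return Normalized label text, or the sentinel.
#' @export
#' @examples
#' normalize_label("HeartAttack")        # "heart attack"
#' normalize_label("the_Heart(organ)")   # "heart organ"
normalize_label <- function(raw, options = parse_options()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (identical(raw, EMPTY_AFTER_PROCESSING)) return(raw)
  s <- raw
  if (options$strip_brackets) {
    s <- if (options$drop_bracketed) {
      gsub("\\([^)]*\\)|\\[[^]]*\\]|\\{[^}]*\\}", " ", s)
    } else {
      gsub("[][(){}]", " ", s)
    }
  }
  if (options$replace_underscores) s <- gsub("_", " ", s, fixed = TRUE)
  if (options$replace_dashes) s <- gsub("-", " ", s, fixed = TRUE)
  if (options$split_camel_case) {
    s <- gsub("(?<=[a-z0-9])(?=[A-Z])", " ", s, perl = TRUE)
    s <- gsub("(?<=[A-Z])(?=[A-Z][a-z])", " ", s, perl = TRUE)
  }
  if (options$lowercase) s <- tolower(s)
  if (options$remove_determiners) {
    s <- gsub("(?i)(?<![A-Za-z0-9])(a|an|the)(?![A-Za-z0-9])", " ", s,
              perl = TRUE)
  }
  s <- trimws(gsub("[[:space:]]+", " ", s))
  if (!nzchar(s)) EMPTY_AFTER_PROCESSING else s
}

#' Split a processed label into tokens
#'
#' @param processed A label from [normalize_label()].
#' @return Character vector of whitespace-free tokens, order preserved;
#'   empty for the empty-after-processing sentinel.
#' @export
tokenize_label <- function(processed) {
  stopifnot(is.character(processed), length(processed) == 1L)
  if (identical(processed, EMPTY_AFTER_PROCESSING)) return(character())
  toks <- strsplit(trimws(processed), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Build processed label records for an ontology
#'
#' Runs label extraction, normalization and tokenization over every entity,
#' producing the grid of original and post-processed labels.
#'
#' @param model An `ontology_model`.
#' @param options A [parse_options()] object.
#' @param label_properties,language_preference Passed to
#'   [extract_labels()].
#' @return Data frame with columns `entity_iri`, `raw_label`,
#'   `processed_label`, plus a `tokens` list column.
#' @export
label_records <- function(model, options = parse_options(),
                          label_properties = IRI_RDFS_LABEL,
                          language_preference = c("", "en")) {
  raw <- extract_labels(model, label_properties, language_preference)
  processed <- vapply(raw$raw_label, normalize_label, "", options = options,
                      USE.NAMES = FALSE)
  out <- data.frame(
    entity_iri = raw$entity_iri,
    raw_label = raw$raw_label,
    processed_label = processed,
    stringsAsFactors = FALSE
  )
  out$tokens <- lapply(processed, tokenize_label)
  out
}

#' Tally token occurrences across all labels
#'
#' Every label contributes each of its tokens once per occurrence;
#' uniqueness is exact text equality after normalization (corpus-wide, not
#' per label).  The duplicate count is `occurrences - t`: each repeat
#' beyond a token's first occurrence counts once, so a fully unique corpus
#' has `d = 0`.
#'
#' @param records A data frame from [label_records()] (needs the `tokens`
#'   column), or a list of token vectors.
#' @return List of class `token_census` with `occurrences`, `t` (unique
#'   tokens), `d` (duplicates) and `per_token_counts`.
#' @export
census_tokens <- function(records) {
  token_lists <- if (is.data.frame(records)) records$tokens else records
  flat <- unlist(token_lists, use.names = FALSE)
  if (is.null(flat)) flat <- character()
  counts <- if (length(flat)) table(flat) else table(character())
  structure(list(
    occurrences = length(flat),
    t = length(counts),
    d = length(flat) - length(counts),
    per_token_counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "token_census")
}
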