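# Full scoring session: configuration -> censuses -> sub-scores -> Q,
# with JSON snapshots and rendered reports.

SNAPSHOT_SCHEMA_VERSION <- 1L

#' Session configuration
#'
#' Collects everything a scoring run needs.  Aspects may be excluded;
#' scores the engine cannot compute itself (relevancy, authority, history)
#' are optional manual inputs in \[0, 1\].  When an optional sub-score is
#' absent its weight is redistributed over the remaining sub-scores of the
#' aspect.
#'
#' @param ontology Path to the ontology file.
#' @param options A [parse_options()].
#' @param mode A [metric_mode()].
#' @param weights A [quality_weights()].
#' @param excluded_aspects Subset of `c("syntactic", "semantic",
#'   "pragmatic", "social")`.  Social is excluded by default: its
#'   sub-scores are manual inputs.
#' @param baseline_average Library-average element count for
#'   comprehensiveness; required when the pragmatic aspect is active.
#' @param relevancy,authority,history Optional manual scores in \[0, 1\].
#' @param lexicon A `lexical_db`; required when the semantic aspect is
#'   active.
#' @param review_files Named character vector of review CSV paths keyed by
#'   reviewer id; feeds accuracy when present.
#' @param review_denominator `"all"` or `"judged"`; see
#'   [accuracy_from_review()].
#' @param label_properties,language_preference Label extraction settings.
#' @param follow_imports,import_map Passed to [merge_imports()].
#' @return List of class `session_config`.
#' @export
score_config <- function(ontology,
                         options = parse_options(),
                         mode = metric_mode(),
                         weights = quality_weights(),
                         excluded_aspects = "social",
                         baseline_average = NULL,
                         relevancy = NULL, authority = NULL, history = NULL,
                         lexicon = NULL,
                         review_files = character(),
                         review_denominator = "all",
                         label_properties = IRI_RDFS_LABEL,
                         language_preference = c("", "en"),
                         follow_imports = FALSE,
                         import_map = character()) {
  for (manual in list(relevancy, authority, history)) {
    if (!is.null(manual) && (manual < 0 || manual > 1)) {
      abort_ontoqc("manual scores must lie in [0, 1]",
                   "ontoqc_parameter_error")
    }
  }
  aspects <- c("syntactic", "semantic", "pragmatic", "social")
  if (!all(excluded_aspects %in% aspects)) {
    abort_ontoqc("unknown aspect in excluded_aspects",
                 "ontoqc_parameter_error")
  }
  active <- setdiff(aspects, excluded_aspects)
  if ("pragmatic" %in% active && is.null(baseline_average)) {
    abort_ontoqc("baseline_average is required while the pragmatic aspect is active",
                 "ontoqc_configuration_error")
  }
  if ("social" %in% active && is.null(authority) && is.null(history)) {
    abort_ontoqc("the social aspect needs manual authority and/or history scores",
                 "ontoqc_configuration_error")
  }
  structure(list(
    ontology = ontology, options = options, mode = mode, weights = weights,
    excluded_aspects = excluded_aspects,
    baseline_average = baseline_average,
    relevancy = relevancy, authority = authority, history = history,
    lexicon = lexicon, review_files = review_files,
    review_denominator = review_denominator,
    label_properties = label_properties,
    language_preference = language_preference,
    follow_imports = follow_imports, import_map = import_map
  ), class = "session_config")
}

#' Read a session configuration from YAML or JSON
#'
#' Recognized top-level keys mirror the [score_config()] arguments, with
#' `parse_options`, `mode` and `weights` given as nested mappings and the
#' lexicon as `lexicon: {backend: fixture|wordnet, path: ...}`.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A `session_config`.
#' @export
read_score_config <- function(path) {
  if (!file.exists(path)) {
    abort_ontoqc(sprintf("config file not found: %s", path),
                 "ontoqc_io_error")
  }
  raw <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  opts <- do.call(parse_options, as.list(raw$parse_options %||% list()))
  mode <- do.call(metric_mode, as.list(raw$mode %||% list()))
  w_args <- raw$weights %||% list()
  weights <- quality_weights(auto_normalize = w_args$auto_normalize %||% TRUE)
  if (!is.null(w_args$aspect)) weights$aspect <- unlist(w_args$aspect)
  for (g in c("syntactic", "semantic", "pragmatic", "social")) {
    if (!is.null(w_args[[g]])) weights[[g]] <- unlist(w_args[[g]])
  }
  lex <- NULL
  if (!is.null(raw$lexicon)) {
    lex <- switch(raw$lexicon$backend %||% "fixture",
      fixture = read_lexicon_csv(raw$lexicon$path),
      wordnet = wordnet_lexicon(raw$lexicon$path),
      abort_ontoqc("unknown lexicon backend", "ontoqc_configuration_error"))
  }
  score_config(
    ontology = raw$ontology,
    options = opts, mode = mode, weights = weights,
    excluded_aspects = raw$excluded_aspects %||% "social",
    baseline_average = raw$baseline_average,
    relevancy = raw$relevancy, authority = raw$authority,
    history = raw$history,
    lexicon = lex,
    review_files = unlist(raw$review_files) %||% character(),
    review_denominator = raw$review_denominator %||% "all",
    follow_imports = raw$follow_imports %||% FALSE
  )
}

#' Run a full scoring session
#'
#' Loads the ontology, runs the label/token/sense pipeline, computes every
#' active sub-score and the weighted composite.  Every intermediate census
#' is recorded in the card's `inputs` digest, so each reported number is
#' traceable.  Deterministic for fixed inputs.
#'
#' @param config A [score_config()].
#' @return List of class `score_card`.
#' @export
build_scorecard <- function(config) {
  stopifnot(inherits(config, "session_config"))
  aspects <- c("syntactic", "semantic", "pragmatic", "social")
  active <- setdiff(aspects, config$excluded_aspects)

  model <- load_ontology(config$ontology)
  model <- merge_imports(model, follow = config$follow_imports,
                         import_map = config$import_map)

  ax_census <- census_axioms(model)
  el_census <- census_elements(model)
  inventory <- survey_features(model)
  violations <- count_dl_violations(model)

  scores <- list()
  raw_scores <- list()
  inputs <- list(
    axioms = unclass(ax_census), elements = unclass(el_census),
    n_features_used = length(inventory$used), violations = violations)

  combine <- function(subs, weights) {
    # subs: named numeric with NA for absent sub-scores
    present <- !is.na(subs)
    if (!any(present)) return(NA_real_)
    aspect_score(subs[present], weights[names(subs)[present]],
                 auto_normalize = TRUE)
  }

  if ("syntactic" %in% active) {
    scores$SL <- lawfulness(ax_census, violations,
                            mode = config$mode$lawfulness_mode)
    scores$SR <- richness(inventory)
    scores$S <- combine(c(SL = scores$SL, SR = scores$SR),
                        config$weights$syntactic)
  }

  if ("semantic" %in% active) {
    if (is.null(config$lexicon)) {
      abort_ontoqc("the semantic aspect needs a lexicon backend",
                   "ontoqc_configuration_error")
    }
    records <- label_records(model, config$options,
                             config$label_properties,
                             config$language_preference)
    tok_census <- census_tokens(records)
    stats <- sense_stats(config$lexicon, tok_census)
    inputs$tokens <- list(occurrences = tok_census$occurrences,
                          t = tok_census$t, d = tok_census$d)
    inputs$senses <- unclass(stats)[c("t_sense", "total_senses",
                                      "t_avg_sense")]
    scores$EI <- interpretability(stats,
                                  mode = config$mode$interpretability_mode)
    raw_scores$EA <- clarity(stats, clamp_to_unit = FALSE)
    raw_scores$EC <- consistency(tok_census, clamp_to_unit = FALSE)
    scores$EA <- clarity(stats, clamp_to_unit = config$mode$clamp_to_unit)
    scores$EC <- consistency(tok_census,
                             clamp_to_unit = config$mode$clamp_to_unit)
    scores$E <- combine(c(EI = scores$EI, EC = scores$EC, EA = scores$EA),
                        config$weights$semantic)
  }

  if ("pragmatic" %in% active) {
    scores$PO <- comprehensiveness(el_census, config$baseline_average)
    if (length(config$review_files)) {
      stmts <- verbalize_ontology(model, config$options,
                                  config$label_properties,
                                  config$language_preference)
      reviews <- lapply(names(config$review_files), function(rid) {
        import_judgments(config$review_files[[rid]], rid, stmts)
      })
      review <- do.call(combine_reviews, reviews)
      acc <- accuracy_from_review(review, ax_census$n_logical,
                                  denominator = config$review_denominator)
      scores$PU <- acc$PU
      inputs$review <- acc$per_reviewer
    } else {
      scores$PU <- NA_real_
    }
    scores$PR <- config$relevancy %||% NA_real_
    scores$P <- combine(c(PO = scores$PO, PU = scores$PU, PR = scores$PR),
                        config$weights$pragmatic)
  }

  if ("social" %in% active) {
    scores$OT <- config$authority %||% NA_real_
    scores$OH <- config$history %||% NA_real_
    scores$O <- combine(c(OT = scores$OT, OH = scores$OH),
                        config$weights$social)
  }

  w <- normalize_weights(config$weights, active)
  scores$Q <- overall_quality(
    S = scores$S %||% NA, E = scores$E %||% NA,
    P = scores$P %||% NA, O = scores$O %||% NA, weights = w)

  structure(list(
    scores = scores,
    raw_scores = raw_scores,
    excluded_aspects = config$excluded_aspects,
    modes = config$mode,
    weights = list(aspect = w$aspect, syntactic = config$weights$syntactic,
                   semantic = config$weights$semantic,
                   pragmatic = config$weights$pragmatic,
                   social = config$weights$social),
    inputs = inputs,
    ontology = config$ontology,
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Save / load a scorecard snapshot
#'
#' JSON round-trip: scores survive to full double precision, and the
#' snapshot embeds the schema version, input digest and a timestamp.
#'
#' @param card A `score_card`.
#' @param path Snapshot path.
#' @return `save_snapshot()` the path, invisibly; `load_snapshot()` a
#'   `score_card`.
#' @export
save_snapshot <- function(card, path) {
  stopifnot(inherits(card, "score_card"))
  payload <- unclass(card)
  payload$schema_version <- SNAPSHOT_SCHEMA_VERSION
  payload$modes <- unclass(payload$modes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) {
    abort_ontoqc(sprintf("snapshot not found: %s", path), "ontoqc_io_error")
  }
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort_ontoqc(
      sprintf("snapshot '%s' is not parseable JSON: %s", path,
              conditionMessage(e)), "ontoqc_parse_error"))
  ver <- payload$schema_version
  if (is.null(ver) || ver != SNAPSHOT_SCHEMA_VERSION) {
    abort_ontoqc(sprintf(
      "snapshot schema version %s does not match supported version %d",
      ver %||% "<missing>", SNAPSHOT_SCHEMA_VERSION),
      "ontoqc_version_error")
  }
  payload$schema_version <- NULL
  payload$scores <- lapply(payload$scores, function(v) {
    if (is.null(v)) NA_real_ else as.numeric(v)
  })
  payload$modes <- structure(payload$modes, class = "metric_mode")
  payload$excluded_aspects <- as.character(payload$excluded_aspects %||%
                                             character())
  structure(payload, class = "score_card")
}

#' Render a scorecard as text or JSON
#'
#' Shows every sub-score with its weight and equation mode, marks excluded
#' aspects, and flags a comprehensiveness score above the library baseline
#' (PO > 1).
#'
#' @param card A `score_card`.
#' @param format `"text"` or `"json"`.
#' @return Character vector of lines (`"text"`) or a JSON string
#'   (`"json"`).
#' @export
render_report <- function(card, format = c("text", "json")) {
  format <- match.arg(format)
  s <- card$scores
  if (format == "json") {
    return(jsonlite::toJSON(list(
      scores = s, excluded_aspects = card$excluded_aspects,
      modes = unclass(card$modes), weights = card$weights,
      flags = list(over_baseline = isTRUE(!is.na(s$PO) && s$PO > 1)),
      inputs = card$inputs
    ), auto_unbox = TRUE, digits = NA, null = "null"))
  }
  fmt <- function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) "-" else sprintf("%.4f", v)
  }
  lines <- c(
    sprintf("Ontology quality scorecard (%s)", card$ontology %||% ""),
    sprintf("  modes: lawfulness=%s interpretability=%s clamp=%s",
            card$modes$lawfulness_mode, card$modes$interpretability_mode,
            card$modes$clamp_to_unit),
    "  syntactic:",
    sprintf("    SL lawfulness        %s", fmt(s$SL)),
    sprintf("    SR richness          %s", fmt(s$SR)),
    sprintf("    S  aspect            %s (weight %.3f)", fmt(s$S),
            card$weights$aspect[["syntactic"]]),
    "  semantic:",
    sprintf("    EI interpretability  %s", fmt(s$EI)),
    sprintf("    EC consistency       %s", fmt(s$EC)),
    sprintf("    EA clarity           %s", fmt(s$EA)),
    sprintf("    E  aspect            %s (weight %.3f)", fmt(s$E),
            card$weights$aspect[["semantic"]]),
    "  pragmatic:",
    sprintf("    PO comprehensiveness %s%s", fmt(s$PO),
            if (!is.null(s$PO) && !is.na(s$PO) && s$PO > 1)
              "  [over baseline]" else ""),
    sprintf("    PU accuracy          %s", fmt(s$PU)),
    sprintf("    PR relevancy         %s", fmt(s$PR)),
    sprintf("    P  aspect            %s (weight %.3f)", fmt(s$P),
            card$weights$aspect[["pragmatic"]]),
    "  social:",
    sprintf("    OT authority         %s", fmt(s$OT)),
    sprintf("    OH history           %s", fmt(s$OH)),
    sprintf("    O  aspect            %s (weight %.3f)", fmt(s$O),
            card$weights$aspect[["social"]]),
    sprintf("  overall quality Q:     %s", fmt(s$Q))
  )
  if (length(card$excluded_aspects)) {
    lines <- c(lines, paste0("  excluded aspects: ",
                             paste(card$excluded_aspects, collapse = ", ")))
  }
  lines
}
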