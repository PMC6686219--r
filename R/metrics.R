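# Semiotic sub-scores and the weighted overall quality score.
#
# Two equation modes exist for lawfulness and interpretability.  The
# "literal" mode evaluates the published formulas exactly as printed
# (SL = violations/AX, EI = 1 - t_sense/t); under them a flawless ontology
# scores 0.  The "classic" mode (default) uses the complemented forms
# (SL = 1 - violations/AX, EI = t_sense/t), consistent with the convention
# that a high score means better.  Both are first-class and recorded in
# every scorecard.

#' Equation-mode settings
#'
#' @param lawfulness_mode,interpretability_mode `"classic"` (complemented,
#'   higher is better; default) or `"literal"` (the printed formula).
#' @param clamp_to_unit Floor clarity and consistency at 0 when duplicates
#'   or average senses push the raw value negative.  Comprehensiveness is
#'   never clamped.
#' @return List of class `metric_mode`.
#' @export
metric_mode <- function(lawfulness_mode = c("classic", "literal"),
                        interpretability_mode = c("classic", "literal"),
                        clamp_to_unit = TRUE) {
  structure(list(
    lawfulness_mode = match.arg(lawfulness_mode),
    interpretability_mode = match.arg(interpretability_mode),
    clamp_to_unit = isTRUE(clamp_to_unit)
  ), class = "metric_mode")
}

#' Lawfulness (SL): DL violations relative to total axioms
#'
#' @param census An `axiom_census` (or anything with `n_total`); must have
#'   `n_total > 0`.
#' @param violations Non-negative violation count from
#'   [count_dl_violations()].
#' @param mode `"classic"` gives `1 - violations/n_total`; `"literal"`
#'   gives `violations/n_total`.
#' @return Numeric score.
#' @export
lawfulness <- function(census, violations, mode = c("classic", "literal")) {
  mode <- match.arg(mode)
  n_total <- if (is.list(census)) census$n_total else census
  if (!is.numeric(n_total) || n_total <= 0) {
    abort_ontoqc("lawfulness undefined: ontology has no axioms",
                 "ontoqc_undefined_score")
  }
  stopifnot(violations >= 0)
  frac <- violations / n_total
  if (mode == "literal") frac else 1 - frac
}

#' Richness (SR): fraction of OWL constructs exercised
#'
#' `SR = |used| / 39`, the catalog size being fixed for OWL.
#'
#' @param inventory A `feature_inventory` from [survey_features()].
#' @return Numeric score in \[0, 1\].
#' @export
richness <- function(inventory) {
  used <- if (is.list(inventory)) inventory$used else inventory
  length(used) / length(owl_feature_catalog())
}

#' Interpretability (EI): sense coverage of unique label tokens
#'
#' @param stats A `sense_stats` object; must have `t > 0`.
#' @param mode `"classic"` gives `t_sense/t`; `"literal"` gives
#'   `1 - t_sense/t`.
#' @return Numeric score in \[0, 1\].
#' @export
interpretability <- function(stats, mode = c("classic", "literal")) {
  mode <- match.arg(mode)
  if (stats$t <= 0) {
    abort_ontoqc("interpretability undefined: no unique tokens",
                 "ontoqc_undefined_score")
  }
  frac <- stats$t_sense / stats$t
  if (mode == "literal") 1 - frac else frac
}

#' Clarity (EA): ambiguity penalty from average sense counts
#'
#' `EA = 1 - t_avg_sense / t`.  The raw value can drop below 0 when the
#' average sense count exceeds the unique-token count; with
#' `clamp_to_unit` it is floored at 0.
#'
#' @param stats A `sense_stats` object; must have `t > 0`.
#' @param clamp_to_unit Floor at 0?
#' @return Numeric score.
#' @export
clarity <- function(stats, clamp_to_unit = TRUE) {
  if (stats$t <= 0) {
    abort_ontoqc("clarity undefined: no unique tokens",
                 "ontoqc_undefined_score")
  }
  raw <- 1 - stats$t_avg_sense / stats$t
  if (clamp_to_unit) max(0, raw) else raw
}

#' Consistency (EC): duplicate-token penalty
#'
#' `EC = 1 - d/t` with `d` the duplicate occurrences and `t` the unique
#' tokens, corpus-wide.  Equals 1 when all tokens are unique; can drop
#' below 0 when duplicates outnumber uniques, and is then floored at 0
#' under `clamp_to_unit`.
#'
#' @param census A `token_census`; must have `t > 0`.
#' @param clamp_to_unit Floor at 0?
#' @return Numeric score.
#' @export
consistency <- function(census, clamp_to_unit = TRUE) {
  if (census$t <= 0) {
    abort_ontoqc("consistency undefined: no unique tokens",
                 "ontoqc_undefined_score")
  }
  raw <- 1 - census$d / census$t
  if (clamp_to_unit) max(0, raw) else raw
}

#' Comprehensiveness (PO): element count against a library baseline
#'
#' `PO = n_elements / baseline_average`.  Deliberately unclamped: with
#' modern ontologies the value may exceed 1, which reports flag rather
#' than hide.  Classic baselines are 500 (the original survey value) or a
#' domain-library average such as 169,862 for a drug-ontology set.
#'
#' @param elements An `element_census` (or a bare element count).
#' @param baseline_average Positive library-average element count.
#' @return Non-negative numeric score, possibly above 1.
#' @export
comprehensiveness <- function(elements, baseline_average) {
  if (!is.numeric(baseline_average) || length(baseline_average) != 1L ||
      is.na(baseline_average) || baseline_average <= 0) {
    abort_ontoqc("baseline_average must be a positive number",
                 "ontoqc_parameter_error")
  }
  n <- if (is.list(elements)) elements$n_elements else elements
  n / baseline_average
}

#' Accuracy (PU): expert-judged truth of verbalized axioms
#'
#' Each reviewer's count of statements judged true is divided by the
#' logical-axiom count; the per-reviewer fractions are averaged.
#'
#' @param true_counts_per_reviewer Integer vector, one count per reviewer.
#' @param n_logical Positive logical-axiom count.
#' @return Numeric score in \[0, 1\].
#' @export
accuracy <- function(true_counts_per_reviewer, n_logical) {
  if (length(true_counts_per_reviewer) == 0L) {
    abort_ontoqc("accuracy undefined: no reviewers", "ontoqc_undefined_score")
  }
  if (!is.numeric(n_logical) || n_logical <= 0) {
    abort_ontoqc("accuracy undefined: no logical axioms",
                 "ontoqc_undefined_score")
  }
  if (any(true_counts_per_reviewer < 0) ||
      any(true_counts_per_reviewer > n_logical)) {
    abort_ontoqc("true counts must lie in [0, n_logical]",
                 "ontoqc_data_error")
  }
  mean(true_counts_per_reviewer / n_logical)
}

#' Weighted combination of sub-scores within one aspect
#'
#' @param sub_scores Numeric vector of active sub-scores.
#' @param weights Non-negative weights, same length.
#' @param auto_normalize Rescale the weights to sum 1 over the active
#'   sub-scores before combining.
#' @return Numeric weighted sum.
#' @export
aspect_score <- function(sub_scores, weights, auto_normalize = TRUE) {
  stopifnot(length(sub_scores) == length(weights), all(weights >= 0))
  if (length(sub_scores) == 0L || sum(weights) == 0) {
    abort_ontoqc("aspect score needs at least one positively weighted sub-score",
                 "ontoqc_parameter_error")
  }
  if (auto_normalize) weights <- weights / sum(weights)
  sum(sub_scores * weights)
}

#' Two-level weight scheme
#'
#' Aspect weights modulate the four semiotic layers in the composite; each
#' layer has its own sub-score weights.  Defaults are equal weights
#' everywhere with auto-normalization on, so excluding an aspect or
#' sub-score redistributes its weight over the remainder.  Explicit,
#' non-normalized weights (e.g. 0.15/0.51/0.33 with social excluded) are
#' passed through untouched when `auto_normalize = FALSE`.
#'
#' @param aspect Named numeric vector `c(syntactic=, semantic=, pragmatic=,
#'   social=)`.
#' @param syntactic Weights `c(SL=, SR=)`.
#' @param semantic Weights `c(EI=, EC=, EA=)`.
#' @param pragmatic Weights `c(PO=, PU=, PR=)`.
#' @param social Weights `c(OT=, OH=)`.
#' @param auto_normalize Rescale active weights to sum 1?
#' @return List of class `quality_weights`.
#' @export
quality_weights <- function(aspect = c(syntactic = 0.25, semantic = 0.25,
                                       pragmatic = 0.25, social = 0.25),
                            syntactic = c(SL = 0.5, SR = 0.5),
                            semantic = c(EI = 1/3, EC = 1/3, EA = 1/3),
                            pragmatic = c(PO = 1/3, PU = 1/3, PR = 1/3),
                            social = c(OT = 0.5, OH = 0.5),
                            auto_normalize = TRUE) {
  w <- list(aspect = aspect, syntactic = syntactic, semantic = semantic,
            pragmatic = pragmatic, social = social,
            auto_normalize = isTRUE(auto_normalize))
  for (g in c("aspect", "syntactic", "semantic", "pragmatic", "social")) {
    if (any(w[[g]] < 0)) {
      abort_ontoqc(sprintf("negative weight in group '%s'", g),
                   "ontoqc_parameter_error")
    }
  }
  structure(w, class = "quality_weights")
}

#' Apply aspect exclusions to a weight scheme
#'
#' Excluded aspects are forced to weight 0.  With auto-normalization the
#' remaining aspect weights are rescaled to sum 1; otherwise the explicit
#' weights pass through unrescaled.
#'
#' @param weights A [quality_weights()] object.
#' @param active_aspects Character subset of `c("syntactic", "semantic",
#'   "pragmatic", "social")`.
#' @return A `quality_weights` object.
#' @export
normalize_weights <- function(weights,
                              active_aspects = c("syntactic", "semantic",
                                                 "pragmatic", "social")) {
  stopifnot(inherits(weights, "quality_weights"))
  w <- weights$aspect
  w[setdiff(names(w), active_aspects)] <- 0
  if (sum(w) == 0) {
    abort_ontoqc("all active aspect weights are zero",
                 "ontoqc_parameter_error")
  }
  if (weights$auto_normalize) w <- w / sum(w)
  weights$aspect <- w
  weights
}

#' Overall quality (Q): weighted composite over the four aspects
#'
#' `Q = w_q1*S + w_q2*E + w_q3*P + w_q4*O`, summed over the aspects that
#' are present.  A nonzero weight on an absent aspect is an error.
#'
#' @param S,E,P,O Aspect scores, or `NA` when the aspect is excluded.
#' @param weights A [quality_weights()] object (its `aspect` slot is
#'   used as-is; call [normalize_weights()] first to apply exclusions).
#' @return Numeric composite score.
#' @export
overall_quality <- function(S = NA, E = NA, P = NA, O = NA, weights) {
  stopifnot(inherits(weights, "quality_weights"))
  scores <- c(syntactic = S, semantic = E, pragmatic = P, social = O)
  w <- weights$aspect[names(scores)]
  missing_weighted <- is.na(scores) & w > 0
  if (any(missing_weighted)) {
    abort_ontoqc(paste0("nonzero weight on absent aspect(s): ",
                        paste(names(scores)[missing_weighted], collapse = ", ")),
                 "ontoqc_parameter_error")
  }
  sum(scores[w > 0] * w[w > 0])
}
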