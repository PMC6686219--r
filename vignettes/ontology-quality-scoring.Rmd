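---
title: "Semiotic quality scoring for OWL ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiotic quality scoring for OWL ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoqc)
```

## The model

`ontoqc` grades an OWL 2 ontology on the semiotic framework, which treats an
ontology as a system of signs and scores it on four layers:

* **syntactic** — is it written lawfully and does it use the language richly?
* **semantic** — are its names interpretable, clear and consistent?
* **pragmatic** — is it comprehensive, accurate and relevant for use?
* **social** — is it trusted and referenced by others?

Each layer is a weighted sum of sub-scores, and the overall quality is a
weighted sum of the layers:

$$Q = w_{q_1} S + w_{q_2} E + w_{q_3} P + w_{q_4} O$$

with

$$S = w_{s_1}\,SL + w_{s_2}\,SR, \qquad
  E = w_{e_1}\,EI + w_{e_2}\,EC + w_{e_3}\,EA, \qquad
  P = w_{p_1}\,PO + w_{p_2}\,PU + w_{p_3}\,PR, \qquad
  O = w_{o_1}\,OT + w_{o_2}\,OH.$$

The sub-scores are computed from four raw censuses of the parsed ontology —
axioms, elements, language features, label tokens — plus a word-sense lookup
against a lexical database and, for accuracy, a table of expert verdicts:

| score | formula | inputs |
|---|---|---|
| lawfulness `SL` | `1 - violations / AX` (classic) | DL-profile violations, all axioms |
| richness `SR` | `|used| / 39` | distinct OWL constructs exercised |
| interpretability `EI` | `t_sense / t` (classic) | unique tokens with ≥ 1 sense |
| consistency `EC` | `1 - d / t` | duplicate token occurrences |
| clarity `EA` | `1 - (t_senses / t) / t` | average senses per unique token |
| comprehensiveness `PO` | `n_elements / baseline` | element count vs. library average |
| accuracy `PU` | mean over reviewers of `true_i / n_logical` | expert verdicts |

Relevancy (`PR`), authority (`OT`) and history (`OH`) cannot be computed from
the ontology alone; they are optional manual inputs in $[0,1]$, and an absent
sub-score has its weight redistributed over the rest of its layer.

## Equation modes

The published lawfulness and interpretability formulas, read literally, are
*penalty fractions*: `SL = violations/AX` is 0 for a flawless ontology, and
`EI = 1 - t_sense/t` *falls* as sense coverage rises.  Both contradict the
convention — stated alongside the same framework — that a high score means
better, and the complemented forms are what the classic semiotic metric
suite uses.  Rather than assert one reading, both are first-class:

* `classic` (default): `SL = 1 - violations/AX`, `EI = t_sense/t`;
* `literal`: the formulas exactly as printed.

The mode is recorded in every scorecard, and the two forms always sum to 1,
which the test suite asserts as an invariant.

## Numerical choices and degenerate inputs

* **Clamping.** Clarity can go negative when the average sense count exceeds
  the unique-token count, and consistency when duplicates outnumber unique
  tokens.  `clamp_to_unit` (default on) floors both at 0; the raw values are
  kept in the scorecard.  Comprehensiveness is deliberately *never* clamped
  — element counts above the library baseline are meaningful and are
  flagged, not hidden.
* **Undefined scores.** An ontology with no axioms has no lawfulness; a
  corpus with no tokens has no semantic scores; a review with no judgments
  has no accuracy.  These raise typed errors rather than returning 0, so a
  missing input is never mistaken for a bad ontology.
* **Duplicate counting.** `d = occurrences - t`, corpus-wide: each repeat
  beyond a token's first occurrence counts once.  This keeps `EC = 1` when
  all tokens are unique and makes `EC` independent of label order.
  Counting corpus-wide (rather than per label) matches a reading of
  "unique words in the ontology".
* **Weights.** With `auto_normalize` on, active weights are rescaled to sum
  to 1, so excluding an aspect equals renormalizing over the remainder and
  `Q` is invariant under positive rescaling of the raw weights.  Explicit
  weight vectors (e.g. the demonstration setting 0.15 / 0.51 / 0.33 with
  social excluded) pass through unrescaled when `auto_normalize = FALSE`.

## The construct catalogs

Richness needs a fixed denominator: the number of features OWL offers,
which is 39.  No published enumeration of those 39 features accompanies the
number, so the package ships an explicit, auditable catalog
(`owl_feature_catalog()`): 28 logical axiom-type constructs plus 11
class-expression constructs.  The catalog is a faithful stand-in chosen
once, not a reconstruction of any particular tool's internal list; what
matters for reproducibility is that the denominator is fixed and the
membership documented.

The verbalizer likewise supports exactly 25 logical axiom types
(`supported_axiom_types()`), covering class axioms, property axioms,
property characteristics, assertions and keys.  Logical axioms outside the
set are counted as unsupported, so
`nrow(statements) + n_unsupported = n_logical` always reconciles.  The
English templates are the package's own (one per type, with recursive
rendering of intersections, unions, existential and universal
restrictions); fidelity to any specific generator's phrasing is a non-goal.
Articles are chosen by an initial-letter heuristic and no pluralization is
attempted — reviewer comprehension, not fluent prose, is the bar.

## Label normalization order

The parsing options only name the rules (camel-case fixing; removal of
determiners, brackets, underscores, dashes); order is pinned here because
it changes outcomes (`"theHeart"` splits before determiner removal only if
camel-case runs first):

1. bracket characters stripped (enclosed text kept; a documented flag drops
   it),
2. underscores and dashes become spaces,
3. camel-case boundaries become spaces,
4. lowercase fold,
5. stand-alone determiners `a`, `an`, `the` removed,
6. whitespace collapsed.

Normalization is idempotent, and a label that normalizes to nothing becomes
an explicit sentinel excluded from token tallies.

## The lexicon

Sense counts come from a pluggable `lexical_db`: deterministic,
case-insensitive, 0 for out-of-vocabulary tokens, aggregated across all
parts of speech, with no lemmatization and no multi-word collocation
lookup (tokens are looked up individually).  `wordnet_lexicon()` reads a
local WordNet `dict` directory; `fixture_lexicon()` /
`read_lexicon_csv()` build the same contract from an explicit mapping, and
are what the test suite uses so it runs with no corpus download.

## What the synthetic generator emulates

`synth_spec()` + `generate_ontology()` produce Turtle ontologies with fully
known censuses: entity counts, a typed axiom recipe, one two-word label per
entity drawn from a seeded vocabulary (camel-cased or underscored), and
optional class/datatype punning injections — the canonical detectable DL
violation.  Output triples are sorted, so a spec is byte-reproducible.
Defaults (8 classes, 4 individuals, 2 object and 1 data property, a
17-axiom recipe, a 17-word vocabulary with two senseless coinages) are
sized like a small curated terminology: large enough to exercise every
pipeline stage, small enough that the 50-seed oracle suites run in
seconds.

What passing tests on these fixtures shows: the censuses, formulas,
round-trips and invariants are correct.  What they do not show: behavior on
the messiness of real ontologies — multilingual labels, enormous imports,
exotic RDF serialisation idioms, annotation conventions beyond
`rdfs:label`/`skos:prefLabel` — beyond the specific cases the unit tests
cover.

## Scope and known limitations

* The RDF readers cover the Turtle and RDF/XML constructs OWL tools emit
  (prefixes, blank-node property lists, collections, typed nodes,
  `parseType="Collection"/"Resource"`), not the full grammars; OBO format,
  SPARQL and reasoning are out of scope.
* DL-profile checking is a documented four-rule subset (punning,
  reserved-vocabulary declarations, undeclared property use, transitive
  properties in cardinality restrictions), not a complete OWL 2 DL
  validator; only the count feeds lawfulness.
* Imports default to *not followed*, with a warning naming the unresolved
  IRIs — scoring is then local to the file, and merging is the explicit
  `follow = TRUE` path (idempotent, de-duplicated union).
* Social-score harvesting from ontology repositories and cross-corpus
  ranking are out of scope; authority and history remain manual inputs.
* Review round-trips replace a server workflow with per-reviewer CSV files;
  how partially completed reviews are counted is a documented choice
  (`denominator = "all"` counts unjudged statements against accuracy,
  `"judged"` does not) with neither asserted as the original behavior.

## A worked session

```{r example}
spec <- synth_spec(seed = 7)
onto <- tempfile(fileext = ".ttl")
generate_ontology(spec, onto)

card <- build_scorecard(score_config(
  ontology = onto,
  baseline_average = 500,
  lexicon = fixture_lexicon(spec$vocabulary)))
card
```

The accuracy tab of the same session exports statements for review and
re-imports verdicts:

```{r review}
stmts <- verbalize_ontology(load_ontology(onto))
head(stmts$statements$sentence, 3)
```
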