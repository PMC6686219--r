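# ontoqc

Semiotic quality scoring for OWL 2 ontologies, in R.

Ontology engineers and curators — particularly in biomedical terminology
work, where ontologies are large, collaboratively built and long-lived —
need a repeatable answer to "how good is this artifact?".  `ontoqc`
implements the semiotic evaluation framework, which grades an ontology as a
system of signs on four layers: **syntactic** (written lawfully, using the
language richly), **semantic** (names that are interpretable, clear and
consistent), **pragmatic** (comprehensive, accurate, relevant) and
**social** (trusted by others).  Each layer is a weighted sum of
sub-scores, and the layers combine into one overall quality score

> Q = w<sub>q1</sub>·S + w<sub>q2</sub>·E + w<sub>q3</sub>·P + w<sub>q4</sub>·O

with S = w<sub>s1</sub>·SL + w<sub>s2</sub>·SR,
E = w<sub>e1</sub>·EI + w<sub>e2</sub>·EC + w<sub>e3</sub>·EA,
P = w<sub>p1</sub>·PO + w<sub>p2</sub>·PU + w<sub>p3</sub>·PR and
O = w<sub>o1</sub>·OT + w<sub>o2</sub>·OH, where

* **SL** lawfulness = 1 − DL-profile violations / all axioms,
* **SR** richness = distinct OWL constructs used / 39 possible,
* **EI** interpretability = unique label tokens with ≥ 1 word sense / unique tokens,
* **EC** consistency = 1 − duplicate token occurrences / unique tokens,
* **EA** clarity = 1 − average senses per unique token / unique tokens,
* **PO** comprehensiveness = element count / library-average baseline (may exceed 1),
* **PU** accuracy = fraction of verbalized logical axioms experts judge true, averaged over reviewers,
* **PR**, **OT**, **OH** are user-supplied manual scores.

The package covers the whole workflow: loading RDF/XML or Turtle
ontologies; censusing axioms, elements and language features; a
configurable label-normalization pipeline (camel-case splitting,
determiner/bracket/underscore/dash handling); pluggable word-sense lookup
(local WordNet directory, or a fixture lexicon for fully offline use);
template-based verbalization of logical axioms into English so domain
experts can mark each statement true or false in a CSV grid; scorecards,
JSON snapshots and reports; plus a deterministic synthetic-ontology
generator used throughout the test suite.  The published lawfulness and
interpretability equations are implemented in both their **literal**
(as-printed) and **classic** (complemented, higher-is-better) forms; the
mode is recorded in every scorecard.

## Worked example

```r
library(ontoqc)

spec <- synth_spec(seed = 7)             # a small ontology with known censuses
onto <- tempfile(fileext = ".ttl")
generate_ontology(spec, onto)

card <- build_scorecard(score_config(
  ontology = onto,
  baseline_average = 500,                # library-average element count
  lexicon = fixture_lexicon(spec$vocabulary)))
card
```

```
Ontology quality scorecard (...)
  modes: lawfulness=classic interpretability=classic clamp=TRUE
  syntactic:
    SL lawfulness        1.0000
    SR richness          0.1795
    S  aspect            0.5897 (weight 0.333)
  semantic:
    EI interpretability  0.8667
    EC consistency       0.0000
    EA clarity           0.7822
    E  aspect            0.5496 (weight 0.333)
  pragmatic:
    PO comprehensiveness 0.0300
    PU accuracy          -
    PR relevancy         -
    P  aspect            0.0300 (weight 0.333)
  social:
    OT authority         -
    OH history           -
    O  aspect            - (weight 0.000)
  overall quality Q:     0.3898
  excluded aspects: social
```

Reading it: no DL violations (SL = 1), 7 of 39 OWL constructs used
(SR ≈ 0.18), 87% of unique label tokens have at least one word sense
(EI), heavy token reuse drives consistency to its floor (EC = 0, raw value
kept in the card), and the 15 elements are tiny against a 500-element
baseline (PO = 0.03).  Accuracy and relevancy are absent, so the pragmatic
layer collapses to PO; social is excluded, so Q averages the three active
layers.

Expert review round-trips through CSV:

```r
stmts <- verbalize_ontology(load_ontology(onto))
head(stmts$statements$sentence, 3)
#> [1] "Every organ zorblex is a cell pressure."
#> [2] "Blood organ is a cell disease."
#> [3] "Failure cell is a blood failure."

export_statements(stmts, "review.csv")      # reviewer fills the verdict column
rs <- import_judgments("review.csv", "reviewer1", stmts)
accuracy_from_review(rs, census_axioms(load_ontology(onto))$n_logical)
```

A thin CLI wraps the same functions
(`exec/ontoqc score --config session.yaml`, `verbalize`, `review-export`,
`review-import`, `snapshot-show`).

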