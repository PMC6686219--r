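# Sub-score formulas, both equation modes, weighting and the composite.

mk_census <- function(n_logical, n_non_logical) {
  structure(list(n_logical = n_logical, n_non_logical = n_non_logical,
                 n_total = n_logical + n_non_logical),
            class = "axiom_census")
}
mk_stats <- function(t, t_sense, total_senses) {
  structure(list(t = t, t_sense = t_sense, total_senses = total_senses,
                 t_avg_sense = total_senses / t), class = "sense_stats")
}
mk_tokens <- function(occurrences, t) {
  structure(list(occurrences = occurrences, t = t, d = occurrences - t,
                 per_token_counts = integer()), class = "token_census")
}

test_that("lawfulness evaluates both modes and rejects empty ontologies", {
  cen <- mk_census(60L, 40L)
  expect_equal(lawfulness(cen, 0, "classic"), 1.0)
  expect_equal(lawfulness(cen, 5, "literal"), 0.05)
  expect_equal(lawfulness(cen, 5, "classic"), 0.95)
  expect_error(lawfulness(mk_census(0L, 0L), 0),
               class = "ontoqc_undefined_score")
})

test_that("richness divides used constructs by the fixed catalog size", {
  expect_equal(richness(list(used = character())), 0)
  expect_equal(richness(list(used = owl_feature_catalog())), 1)
  expect_equal(richness(list(used = owl_feature_catalog()[1:13])), 13 / 39)
})

test_that("interpretability evaluates both modes", {
  expect_equal(interpretability(mk_stats(10L, 10L, 20L), "literal"), 0)
  expect_equal(interpretability(mk_stats(10L, 10L, 20L), "classic"), 1)
  expect_equal(interpretability(mk_stats(4L, 3L, 6L), "literal"), 0.25)
  expect_equal(interpretability(mk_stats(4L, 0L, 0L), "classic"), 0)
})

test_that("clarity penalizes average ambiguity and clamps at zero", {
  expect_equal(clarity(mk_stats(5L, 5L, 10L)), 0.6)
  expect_equal(clarity(mk_stats(5L, 0L, 0L)), 1.0)
  expect_equal(clarity(mk_stats(2L, 2L, 10L)), 0)
  expect_equal(clarity(mk_stats(2L, 2L, 10L), clamp_to_unit = FALSE), -1.5)
})

test_that("consistency penalizes duplicates and clamps at zero", {
  expect_equal(consistency(mk_tokens(5L, 5L)), 1.0)
  expect_equal(consistency(mk_tokens(3L, 2L)), 0.5)
  expect_equal(consistency(mk_tokens(30L, 10L)), 0)
  expect_equal(consistency(mk_tokens(30L, 10L), clamp_to_unit = FALSE), -1.0)
})

test_that("comprehensiveness is a plain unclamped ratio to the baseline", {
  expect_equal(comprehensiveness(list(n_elements = 100L), 500), 0.2)
  expect_equal(comprehensiveness(list(n_elements = 1000000L), 169862),
               1000000 / 169862)
  expect_gt(comprehensiveness(list(n_elements = 1000000L), 169862), 1)
  expect_equal(comprehensiveness(list(n_elements = 0L), 500), 0)
  expect_error(comprehensiveness(list(n_elements = 10L), 0),
               class = "ontoqc_parameter_error")
})

test_that("accuracy averages per-reviewer true fractions", {
  expect_equal(accuracy(c(8, 6), 10), 0.7)
  expect_equal(accuracy(10, 10), 1.0)
  expect_equal(accuracy(c(0, 0, 0), 5), 0)
  expect_error(accuracy(integer(), 10), class = "ontoqc_undefined_score")
  expect_error(accuracy(11, 10), class = "ontoqc_data_error")
})

test_that("aspect scores combine sub-scores with optional normalization", {
  expect_equal(aspect_score(c(1, 1), c(0.5, 0.5)), 1.0)
  expect_equal(aspect_score(c(0.8, 0.4), c(0.5, 0.5)), 0.6)
  expect_equal(aspect_score(c(0.9, 0.3, 0.6), c(1, 1, 1)), 0.6)
  expect_error(aspect_score(c(1, 1), c(0, 0)),
               class = "ontoqc_parameter_error")
})

test_that("weight normalization respects exclusions and explicit weights", {
  w <- quality_weights()
  n <- normalize_weights(w, c("syntactic", "semantic", "pragmatic"))
  expect_equal(unname(n$aspect),
               c(1 / 3, 1 / 3, 1 / 3, 0))

  demo <- quality_weights(aspect = c(syntactic = 0.15, semantic = 0.51,
                                     pragmatic = 0.33, social = 0),
                          auto_normalize = FALSE)
  kept <- normalize_weights(demo, c("syntactic", "semantic", "pragmatic"))
  expect_equal(unname(kept$aspect), c(0.15, 0.51, 0.33, 0))

  all4 <- normalize_weights(quality_weights())
  expect_equal(unname(all4$aspect), rep(0.25, 4))

  expect_error(normalize_weights(quality_weights(), character()),
               class = "ontoqc_parameter_error")
  expect_error(quality_weights(aspect = c(syntactic = -1, semantic = 1,
                                          pragmatic = 1, social = 1)),
               class = "ontoqc_parameter_error")
})

test_that("overall quality is the weighted aspect sum", {
  demo <- quality_weights(aspect = c(syntactic = 0.15, semantic = 0.51,
                                     pragmatic = 0.33, social = 0),
                          auto_normalize = FALSE)
  expect_equal(overall_quality(S = 1, E = 1, P = 1, weights = demo), 0.99)
  zero <- quality_weights()
  expect_equal(overall_quality(0, 0, 0, 0, weights = zero), 0)
  expect_error(
    overall_quality(S = 1, E = 1, P = 1, weights = quality_weights()),
    class = "ontoqc_parameter_error")  # social weighted but absent
})

test_that("overall quality equals a brute-force dot product on random input", {
  set.seed(99)
  for (k in 1:1000) {
    scores <- runif(4)
    raw_w <- runif(4)
    w <- quality_weights(aspect = c(syntactic = raw_w[1], semantic = raw_w[2],
                                    pragmatic = raw_w[3], social = raw_w[4]),
                         auto_normalize = FALSE)
    q <- overall_quality(scores[1], scores[2], scores[3], scores[4],
                         weights = w)
    expect_equal(q, sum(scores * raw_w), tolerance = 1e-12)
  }
})

test_that("literal and classic complements sum to one", {
  set.seed(5)
  for (k in 1:50) {
    n_total <- sample(10:500, 1)
    v <- sample(0:n_total, 1)
    cen <- mk_census(n_total, 0L)
    expect_equal(lawfulness(cen, v, "literal") + lawfulness(cen, v, "classic"),
                 1, tolerance = 1e-12)
    t <- sample(1:200, 1)
    ts <- sample(0:t, 1)
    st <- mk_stats(t, ts, ts * 2L)
    expect_equal(interpretability(st, "literal") +
                   interpretability(st, "classic"), 1, tolerance = 1e-12)
  }
})

test_that("overall quality is monotone in each aspect score", {
  set.seed(21)
  w <- quality_weights(aspect = c(syntactic = 0.2, semantic = 0.4,
                                  pragmatic = 0.3, social = 0.1),
                       auto_normalize = FALSE)
  for (k in 1:100) {
    base <- runif(4)
    q0 <- overall_quality(base[1], base[2], base[3], base[4], weights = w)
    for (i in 1:4) {
      bumped <- base
      bumped[i] <- bumped[i] + runif(1)
      q1 <- overall_quality(bumped[1], bumped[2], bumped[3], bumped[4],
                            weights = w)
      expect_gte(q1, q0)
    }
  }
})

test_that("with auto-normalization Q is invariant under weight rescaling", {
  set.seed(31)
  for (k in 1:50) {
    scores <- runif(4)
    raw <- runif(4, 0.1, 2)
    scale <- runif(1, 0.1, 10)
    q1 <- overall_quality(scores[1], scores[2], scores[3], scores[4],
      weights = normalize_weights(quality_weights(
        aspect = c(syntactic = raw[1], semantic = raw[2],
                   pragmatic = raw[3], social = raw[4]))))
    q2 <- overall_quality(scores[1], scores[2], scores[3], scores[4],
      weights = normalize_weights(quality_weights(
        aspect = c(syntactic = raw[1] * scale, semantic = raw[2] * scale,
                   pragmatic = raw[3] * scale, social = raw[4] * scale))))
    expect_equal(q1, q2, tolerance = 1e-12)
  }
})

test_that("excluding an aspect equals renormalizing over the remainder", {
  set.seed(41)
  for (k in 1:50) {
    scores <- runif(3)
    raw <- runif(3, 0.1, 2)
    w_excl <- normalize_weights(quality_weights(
      aspect = c(syntactic = raw[1], semantic = raw[2], pragmatic = raw[3],
                 social = runif(1))),
      active_aspects = c("syntactic", "semantic", "pragmatic"))
    q_excl <- overall_quality(scores[1], scores[2], scores[3], weights = w_excl)
    q_direct <- sum(scores * raw / sum(raw))
    expect_equal(q_excl, q_direct, tolerance = 1e-12)
  }
})
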