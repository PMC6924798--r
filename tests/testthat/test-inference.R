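# independent step-through of Holm's definition, used as the oracle
holm_by_definition <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

test_that("Holm adjustment matches its step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)            # m = 1: unchanged
  expect_equal(holm_adjust(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_by_definition(p))
    expect_true(all(adj >= p))                    # never below raw
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))             # monotone in raw order
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BIC follows k ln(n) - 2 LL and is monotone in k", {
  expect_equal(bic(-100, 0, 10), 200)
  expect_equal(bic(-100, 5, 155), 5 * log(155) + 200)
  ks <- 0:10
  expect_true(!is.unsorted(vapply(ks, function(k) bic(-50, k, 40),
                                  numeric(1))))
  expect_error(bic(-10, 2, 0))
})

test_that("odds ratios reproduce the published worked examples", {
  p <- reference_parameters()
  sch <- aac_scheme()
  motivated <- child_vignette(sch, determination = "motivated_via_symbols")
  progressing <- child_vignette(sch, predicted_future = "progression")
  favourable <- child_vignette(
    sch, language = "receptive_exceeds_expressive",
    communication_ability = "range_of_functions",
    determination = "motivated_via_symbols",
    predicted_future = "progression")

  # interaction-only contrasts against the baseline vignette; published
  # values were exponentiated from unrounded coefficients, so compare at
  # the precision the rounding chain supports (~0.5%)
  expect_equal(odds_ratio(p, "vocabulary_organisation.taxonomic",
                          motivated, versus = "baseline_vignette"),
               2.03, tolerance = 0.005)
  expect_equal(odds_ratio(p, "vocabulary_organisation.semantic_syntactic",
                          motivated, versus = "baseline_vignette"),
               2.29, tolerance = 0.005)
  expect_equal(odds_ratio(p, "graphical_representation.ideographic",
                          motivated, versus = "baseline_vignette"),
               5.31, tolerance = 0.005)
  expect_equal(odds_ratio(p, "graphical_representation.text", motivated,
                          versus = "baseline_vignette"),
               4.00, tolerance = 0.005)
  expect_equal(odds_ratio(p, "vocabulary_sets.staged_progression",
                          progressing, versus = "baseline_vignette"),
               3.88, tolerance = 0.005)

  # level-vs-baseline contrasts
  expect_equal(odds_ratio(p, "size_of_vocabulary.over_1000"),
               0.395, tolerance = 0.005)
  expect_equal(odds_ratio(p, "size_of_vocabulary.over_1000", favourable),
               22.5, tolerance = 0.005)
})

test_that("odds ratios degenerate correctly and validate inputs", {
  sch <- aac_scheme()
  nil <- mixl_parameters(sch)
  for (lev in c("vocabulary_sets.fixed", "graphical_representation.text"))
    expect_equal(odds_ratio(nil, lev,
                            child_vignette(sch,
                                           predicted_future = "plateau")),
                 1.0)
  expect_error(odds_ratio(nil, "vocabulary_sets.none"), "non-baseline")
  expect_error(odds_ratio(nil, "no_such.level"), "non-baseline")
})
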