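test_that("attention explanations form a simplex and obey the bond rule", {
  sm <- small_model()
  for (s in sm$test$smiles[1:8]) {
    ex <- attention_explanation(sm$model, s)
    expect_equal(sum(ex$atoms$weight), 1, tolerance = 1e-6)
    expect_true(all(ex$atoms$weight >= 0))
    if (nrow(ex$bonds) > 0) {
      for (b in seq_len(nrow(ex$bonds))) {
        expect_equal(ex$bonds$weight[b],
                     mean(ex$atoms$weight[c(ex$bonds$u[b], ex$bonds$v[b])]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a single-edge graph gets the exact one-player Shapley value", {
  sm <- small_model()
  sh <- edge_shapley(sm$model, "CO", n_samples = 5, seed = 3)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$phi, attr(sh, "f_full") - attr(sh, "f_empty"),
               tolerance = 1e-12)
  expect_equal(sh$se, 0, tolerance = 1e-12)   # identical marginals
})

test_that("permutation sampling satisfies the efficiency axiom", {
  sm <- small_model()
  for (s in sm$test$smiles[1:5]) {
    sh <- edge_shapley(sm$model, s, n_samples = 60, seed = 4)
    gap <- abs(sum(sh$phi) - (attr(sh, "f_full") - attr(sh, "f_empty")))
    se_sum <- sqrt(sum(sh$se^2))
    expect_lte(gap, max(3 * se_sum, 1e-10), label = s)
  }
})

test_that("automorphic edges receive statistically equal Shapley values", {
  sm <- small_model()
  # butane C1-C2-C3-C4: the two terminal bonds map onto each other
  sh <- edge_shapley(sm$model, "CCCC", n_samples = 400, seed = 5)
  expect_equal(nrow(sh), 3L)
  outer_rows <- which((sh$u == 1 & sh$v == 2) | (sh$u == 3 & sh$v == 4))
  expect_equal(length(outer_rows), 2L)
  diff <- abs(sh$phi[outer_rows[1]] - sh$phi[outer_rows[2]])
  se <- sqrt(sum(sh$se[outer_rows]^2))
  expect_lte(diff, 3 * se)
})

test_that("standard errors shrink like 1 / sqrt(n_samples)", {
  sm <- small_model()
  s <- sm$test$smiles[1]
  lo <- edge_shapley(sm$model, s, n_samples = 100, seed = 6)
  hi <- edge_shapley(sm$model, s, n_samples = 1600, seed = 6)
  ratio <- mean(hi$se) / mean(lo$se)
  expect_lt(ratio, 0.5)    # expected 1/4
  expect_gt(ratio, 0.1)
})

test_that("Shapley estimation is deterministic under a fixed seed", {
  sm <- small_model()
  s <- sm$test$smiles[2]
  a <- edge_shapley(sm$model, s, n_samples = 40, seed = 7)
  b <- edge_shapley(sm$model, s, n_samples = 40, seed = 7)
  expect_identical(a$phi, b$phi)
})

test_that("the frequency report counts thresholded substructures by class", {
  sm <- small_model()
  ex <- explain_molecules(sm$model, sm$test$smiles[1:6], n_samples = 40,
                          seed = 8)
  # empty when nothing passes an impossible threshold
  empty <- group_frequency_report(ex, threshold = 10)
  expect_equal(nrow(empty), 0L)
  rep <- group_frequency_report(ex, threshold = 0.01, top = 5)
  if (nrow(rep) > 0) {
    expect_true(all(rep$count >= 1))
    expect_true(all(rep$percent > 0 & rep$percent <= 100))
    expect_true(all(rep$class %in% c("stable", "unstable")))
    for (cl in unique(rep$class)) {
      expect_lte(nrow(rep[rep$class == cl, ]), 5L)
    }
  }
  expect_equal(nrow(group_frequency_report(list())), 0L)
})

test_that("a planted dominant motif ranks first for the stable class", {
  sm <- small_model()
  pos <- sm$test[sm$test$clean_label == 1, ]
  pred <- predict(sm$model, pos)
  correct <- pos[pred$class == 1, ]
  expect_gt(nrow(correct), 2)
  ex <- explain_molecules(sm$model, correct$smiles, n_samples = 60, seed = 9)
  rep <- group_frequency_report(ex, threshold = 0.02, top = 10)
  stable <- rep[rep$class == "stable", ]
  expect_gt(nrow(stable), 0)
  stab_names <- c("acetylene", "trifluoromethyl", "trifluoromethylbenzene",
                  "chlorobenzene", "phenyl ring", "alkylbenzene",
                  "alkyl chain", "ring")
  expect_true(stable$group[1] %in% stab_names)
})
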