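test_that("generation is deterministic under a fixed seed", {
  d1 <- synth_molecules(300, noise = 0.1, seed = 7)
  d2 <- synth_molecules(300, noise = 0.1, seed = 7)
  expect_identical(d1, d2)
  d3 <- synth_molecules(300, noise = 0.1, seed = 8)
  expect_false(identical(d1$smiles, d3$smiles))
})

test_that("without noise, labels equal the planted-motif rule", {
  d <- synth_molecules(400, noise = 0, seed = 9)
  stab <- c("acetylene", "trifluoromethyl", "chlorophenyl")
  expect_equal(d$label, d$clean_label)
  expect_equal(d$clean_label, as.integer(d$motif %in% stab))
  expect_false(any(d$flipped))
})

test_that("label noise flips roughly the requested fraction", {
  d <- synth_molecules(2000, noise = 0.1, seed = 10)
  flipped <- mean(d$label != d$clean_label)
  expect_gt(flipped, 0.06)
  expect_lt(flipped, 0.14)
})

test_that("class balance tracks positive_fraction within binomial bounds", {
  n <- 2000
  d <- synth_molecules(n, positive_fraction = 0.64, noise = 0, seed = 11)
  n_pos <- sum(d$clean_label)
  bound <- 3 * sqrt(n * 0.64 * 0.36)
  expect_gt(n_pos, 0.64 * n - bound)
  expect_lt(n_pos, 0.64 * n + bound)
})

test_that("every generated SMILES parses and the motif indices are valid", {
  d <- synth_molecules(500, noise = 0, seed = 12)
  for (i in seq_len(nrow(d))) {
    g <- smiles_to_graph(d$smiles[i])
    idx <- d$motif_atoms[[i]]
    expect_true(all(idx >= 1 & idx <= g$n_nodes), info = d$smiles[i])
    # motif atoms really are the planted group: trifluoromethyl ends in F
    if (d$motif[i] == "trifluoromethyl") {
      expect_equal(sum(g$atoms$symbol[idx] == "F"), 3L, info = d$smiles[i])
    }
    if (d$motif[i] == "hydroxyl") {
      expect_equal(g$atoms$symbol[idx], "O")
      expect_equal(g$atoms$n_hydrogens[idx], 1L)
    }
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(synth_molecules(5), "n >= 10")
  expect_error(synth_molecules(100, noise = 0.6), "noise")
})

test_that("fixture graphs have their documented shapes", {
  fg <- fixture_graphs()
  expect_equal(fg$path3$n_nodes, 3L)
  expect_equal(nrow(fg$path3$edges), 2L)
  expect_equal(fg$benzene$n_nodes, 6L)
  expect_equal(nrow(fg$benzene$edges), 6L)
  expect_equal(fg$singleton$n_nodes, 1L)
  expect_equal(nrow(fg$singleton$edges), 0L)
  expect_equal(fg$two_component$n_nodes, 4L)
  expect_equal(nrow(fg$two_component$edges), 2L)
})
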