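test_that("simple molecules give the expected graphs", {
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_nodes, 1L)
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(g1$features[1, 84], 0)      # aromatic flag off

  g2 <- smiles_to_graph("CCO")
  expect_equal(g2$n_nodes, 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$atoms$n_hydrogens, c(3L, 2L, 1L))

  g3 <- smiles_to_graph("c1ccccc1")
  expect_equal(g3$n_nodes, 6L)
  expect_equal(nrow(g3$edges), 6L)
  expect_true(all(g3$features[, 84] == 1))  # all aromatic
  expect_true(all(g3$atoms$n_hydrogens == 1L))
})

test_that("feature rows are one-hot per block with a binary aromatic flag", {
  d <- synth_molecules(200, noise = 0, seed = 21)
  blocks <- list(1:50, 51:61, 62:72, 73:83)
  for (s in d$smiles[1:50]) {
    f <- smiles_to_graph(s)$features
    expect_equal(ncol(f), 84L)
    for (b in blocks) {
      expect_true(all(rowSums(f[, b, drop = FALSE]) == 1), info = s)
    }
    expect_true(all(f[, 84] %in% c(0, 1)), info = s)
  }
})

test_that("graph chemistry matches known molecules", {
  # paracetamol: acetamide N bridges methylcarbonyl and phenol ring
  g <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1")
  expect_equal(g$n_nodes, 11L)
  expect_equal(sum(g$atoms$aromatic), 6L)
  n_row <- which(g$atoms$symbol == "N")
  expect_equal(g$atoms$degree[n_row], 2L)
  expect_equal(g$atoms$n_hydrogens[n_row], 1L)
  # quaternary ammonium keeps its bracket hydrogen count (none)
  q <- smiles_to_graph("C[N+](C)(C)C")
  expect_equal(q$atoms$n_hydrogens[q$atoms$symbol == "N"], 0L)
  expect_equal(q$atoms$charge[q$atoms$symbol == "N"], 1L)
  # pyrrole NH comes from the bracket atom
  p <- smiles_to_graph("c1cc[nH]c1")
  expect_equal(p$atoms$n_hydrogens[p$atoms$symbol == "N"], 1L)
})

test_that("edges are stored once per unordered pair with valid endpoints", {
  d <- synth_molecules(100, noise = 0, seed = 31)
  for (s in d$smiles[1:30]) {
    g <- smiles_to_graph(s)
    e <- g$edges
    if (nrow(e) == 0) next
    expect_true(all(e[, 1] < e[, 2]), info = s)
    expect_true(all(e >= 1 & e <= g$n_nodes), info = s)
    expect_equal(anyDuplicated(e), 0L, info = s)
  }
})

test_that("unparseable SMILES raise errors carrying the molecule id", {
  expect_error(smiles_to_graph("C1CC", id = "mol42"), "mol42")
  expect_error(smiles_to_graph("C(("), "no atoms|unbalanced|unexpected")
  expect_error(smiles_to_graph("C)C"), "unbalanced")
})

test_that("make_graph validates edges", {
  expect_error(make_graph(matrix(1, 2, 1), rbind(c(1L, 3L))), "out of range")
  expect_error(make_graph(matrix(1, 2, 1), rbind(c(1L, 1L))), "self-loop")
  g <- make_graph(matrix(1:4, 4, 1), rbind(c(1L, 2L), c(2L, 1L)))
  expect_equal(nrow(g$edges), 1L)   # duplicate direction collapsed
})
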