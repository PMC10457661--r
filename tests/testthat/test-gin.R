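test_that("aggregation follows (1 + eps) * self + neighbor sum", {
  fg <- fixture_graphs()
  expect_equal(as.numeric(gin_aggregate(fg$path3$features, fg$path3$edges, 0)),
               c(3, 6, 5))
  expect_equal(as.numeric(gin_aggregate(fg$singleton$features,
                                        fg$singleton$edges, 0.5)),
               7.5)
  expect_equal(as.numeric(gin_aggregate(fg$two_component$features,
                                        fg$two_component$edges, 0)),
               c(3, 3, 7, 7))
  expect_error(gin_aggregate(matrix(1, 2, 1), rbind(c(1L, 5L))),
               "out of range")
})

random_graph <- function(n, d = 3) {
  n_e <- sample.int(max(1, n * (n - 1) / 2), 1)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  e <- pairs[sample.int(nrow(pairs), min(n_e, nrow(pairs))), , drop = FALSE]
  make_graph(matrix(rnorm(n * d), n, d), e)
}

test_that("gin_layer with a random MLP matches the per-node loop oracle", {
  set.seed(10)
  for (trial in 1:50) {
    n <- sample(2:12, 1)
    g <- random_graph(n)
    eps <- rnorm(1)
    mlp <- cmms:::gin_layer_init(3L, 5L)
    mlp$lin2$W <- matrix(rnorm(25), 5, 5)
    mlp$lin2$b <- rnorm(5)
    mlp$bn$gamma <- runif(5, 0.5, 2)
    mlp$bn$beta <- rnorm(5)
    state <- cmms:::bn_state_init(5L)
    got <- gin_layer(g$features, g$edges, eps, mlp, state, training = FALSE)
    want <- gin_layer_oracle(g$features, g$edges, eps, mlp, state)
    expect_equal(got, want, tolerance = 1e-5, info = paste("trial", trial))
  }
})

test_that("encode_graph is invariant to node relabeling", {
  set.seed(11)
  params <- cmms:::gin_init(4L, 6L, 2L)
  g <- random_graph(9, d = 4)
  base <- encode_graph(g, params)
  for (trial in 1:100) {
    perm <- sample.int(9)
    inv <- order(perm)
    g2 <- make_graph(g$features[perm, , drop = FALSE],
                     cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]))
    expect_equal(encode_graph(g2, params), base, tolerance = 1e-5)
  }
})

test_that("node states only see K-hop neighborhoods", {
  set.seed(12)
  params <- cmms:::gin_init(1L, 4L, 2L)
  state <- cmms:::gin_state_init(4L, 2L)
  # path 1-2-3-4-5-6: node 6 is 5 hops from node 1 (> K = 2)
  feats <- matrix(as.numeric(1:6), 6, 1)
  edges <- cbind(1:5, 2:6)
  bg <- cmms:::batch_graphs(list(make_graph(feats, edges)))
  h1 <- cmms:::gin_fwd(bg, params, state, training = FALSE)$node_reps
  feats2 <- feats
  feats2[6, ] <- 100
  bg2 <- cmms:::batch_graphs(list(make_graph(feats2, edges)))
  h2 <- cmms:::gin_fwd(bg2, params, state, training = FALSE)$node_reps
  expect_equal(h1[1, ], h2[1, ], tolerance = 1e-12)  # out of reach
  expect_false(isTRUE(all.equal(h1[6, ], h2[6, ])))
  expect_false(isTRUE(all.equal(h1[4, ], h2[4, ])))  # 2 hops: visible
})

test_that("single-node graphs pool to max == mean", {
  set.seed(13)
  params <- cmms:::gin_init(1L, 5L, 2L)
  p <- encode_graph(fixture_graphs()$singleton, params)
  expect_equal(length(p), 10L)
  expect_equal(p[1:5], p[6:10], tolerance = 1e-12)
})

test_that("one shared encoder processes originals and augmented subgraphs", {
  set.seed(14)
  cfg <- tiny_config(lambda = 0.5)
  params <- cmms:::model_params_init(cfg)
  state <- list(gin = cmms:::gin_state_init(cfg$d_g, cfg$K))
  d <- synth_molecules(10, seed = 3)
  graphs <- lapply(d$smiles[1:4], smiles_to_graph)
  Zs <- lapply(d$smiles[1:4], function(s) {
    matrix(rnorm(length(tokenize_smiles(s)) * cfg$d1), ncol = cfg$d1)
  })
  items <- list(Zs = Zs, graphs = graphs, labels = c(1, 0, 1, 0),
                mask_vector = colMeans(graphs[[1]]$features))
  fwd <- cmms:::model_fwd(params, state, items, cfg, training = TRUE)
  # both views travel through the same block-diagonal batch -> same weights
  expect_equal(fwd$cache$bg$n_graphs, 8L)
  expect_equal(nrow(fwd$cache$gfwd$p), 8L)
})
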