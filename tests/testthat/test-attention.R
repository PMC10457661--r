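test_that("attention weights form a simplex per head", {
  set.seed(6)
  params <- cmms:::attention_init(10L, 4L, 3L, 5L)
  for (m in c(1, 4, 15)) {
    H <- matrix(rnorm(m * 10), m, 10)
    ap <- attention_pool(H, params)
    expect_equal(dim(ap$attention), c(3L, m))
    expect_true(all(ap$attention >= 0))
    expect_equal(rowSums(ap$attention), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("identical hidden rows receive uniform weights 1/m", {
  set.seed(7)
  params <- cmms:::attention_init(8L, 4L, 2L, 5L)
  m <- 6
  H <- matrix(rep(rnorm(8), each = m), m, 8)
  ap <- attention_pool(H, params)
  expect_equal(unname(ap$attention),
               matrix(1 / m, 2, m), tolerance = 1e-10)
})

test_that("raw scores (1, 0) softmax to (e, 1)/(e + 1)", {
  # one head, 1-d hidden, 1-d scoring: u = tanh(h), e = 2u
  params <- list(heads = list(list(W1 = matrix(1, 1, 1), b1 = 0,
                                   w2 = matrix(2, 1, 1))),
                 fcs = list(W = matrix(1, 1, 1), b = 0))
  H <- matrix(c(atanh(0.5), 0), 2, 1)
  ap <- attention_pool(H, params)
  expect_equal(ap$attention[1, ], c(exp(1), 1) / (exp(1) + 1),
               tolerance = 1e-10)
})

test_that("with identity FCs the pooled vector is the attention average", {
  set.seed(8)
  d2 <- 6L
  params <- cmms:::attention_init(d2, 4L, 2L, d2)
  params$fcs$W <- diag(d2)
  params$fcs$b <- rep(0, d2)
  m <- 5
  H <- abs(matrix(rnorm(m * d2), m, d2))   # positive: ReLU inactive
  ap <- attention_pool(H, params)
  manual <- rep(0, d2)
  for (k in 1:2) {
    ctx <- rep(0, d2)
    for (t in seq_len(m)) ctx <- ctx + ap$attention[k, t] * H[t, ]
    manual <- manual + ctx / 2
  }
  expect_equal(ap$seq_rep, manual, tolerance = 1e-10)
})

test_that("every model parameter block receives gradient on a random batch", {
  set.seed(9)
  cfg <- tiny_config(lambda = 0.3)
  params <- cmms:::model_params_init(cfg)
  state <- list(gin = cmms:::gin_state_init(cfg$d_g, cfg$K))
  d <- synth_molecules(12, seed = 13)
  graphs <- lapply(d$smiles[1:6], smiles_to_graph)
  Zs <- lapply(d$smiles[1:6], function(s) {
    matrix(rnorm(length(tokenize_smiles(s)) * cfg$d1), ncol = cfg$d1)
  })
  items <- list(Zs = Zs, graphs = graphs, labels = c(1, 0, 1, 0, 1, 0),
                mask_vector = colMeans(graphs[[1]]$features))
  out <- cmms:::model_loss_grads(params, state, items, cfg, training = TRUE)
  walk <- function(g, path) {
    if (is.list(g)) {
      for (nm in seq_along(g)) {
        walk(g[[nm]], c(path, if (!is.null(names(g))) names(g)[nm]
                        else nm))
      }
    } else {
      expect_true(any(g != 0),
                  info = paste("zero gradient at", paste(path,
                                                         collapse = "$")))
    }
  }
  walk(out$grads, character(0))
})
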