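toy_corpus <- function(n = 60) {
  d <- synth_molecules(n, noise = 0, seed = 5)
  tokenize_smiles(d$smiles)
}

test_that("embedding vectors have the requested dimension for every token", {
  corp <- toy_corpus()
  tab <- train_atom_embeddings(corp, d1 = 100, epochs = 2, seed = 1)
  expect_s3_class(tab, "embedding_table")
  expect_equal(ncol(tab$vectors), 100L)
  expect_true(all(sort(unique(unlist(corp))) %in% names(tab$vocab)))
  expect_true(all(is.finite(tab$vectors)))
})

test_that("training is bitwise deterministic under a fixed seed", {
  corp <- toy_corpus()
  t1 <- train_atom_embeddings(corp, d1 = 32, epochs = 3, seed = 9)
  t2 <- train_atom_embeddings(corp, d1 = 32, epochs = 3, seed = 9)
  expect_identical(t1$vectors, t2$vectors)
  expect_identical(t1$vocab, t2$vocab)
  t3 <- train_atom_embeddings(corp, d1 = 32, epochs = 3, seed = 10)
  expect_false(identical(t1$vectors, t3$vectors))
})

test_that("tokens sharing contexts end up closer than tokens that never do", {
  corp <- c(rep(list(c("A", "X", "B"), c("A", "Y", "B")), 40),
            rep(list(c("Q", "W", "R")), 40))
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  gaps <- vapply(1:5, function(s) {
    tb <- train_atom_embeddings(corp, d1 = 16, epochs = 100, seed = s)
    v <- tb$vectors
    cs(v[tb$vocab[["X"]], ], v[tb$vocab[["Y"]], ]) -
      cs(v[tb$vocab[["X"]], ], v[tb$vocab[["W"]], ])
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("sequence embedding looks up rows and handles OOV tokens", {
  corp <- toy_corpus()
  tab <- train_atom_embeddings(corp, d1 = 24, epochs = 1, seed = 2)
  toks <- c("C", "[Zz]", "O")
  Z <- embed_sequence(toks, tab)
  expect_equal(dim(Z), c(3L, 24L))
  expect_equal(Z[1, ], unname(tab$vectors[tab$vocab[["C"]], ]))
  expect_equal(Z[3, ], unname(tab$vectors[tab$vocab[["O"]], ]))
  # OOV rows are deterministic and depend only on token + oov_seed
  Z2 <- embed_sequence(toks, tab)
  expect_identical(Z[2, ], Z2[2, ])
  expect_true(all(abs(Z[2, ]) <= 0.05))
  tab_other <- tab
  tab_other$oov_seed <- 99L
  expect_false(identical(Z[2, ],
                         embed_sequence(toks, tab_other)[2, ]))
})

test_that("tables round-trip through word2vec text format", {
  corp <- toy_corpus(30)
  tab <- train_atom_embeddings(corp, d1 = 16, epochs = 1, seed = 4)
  p <- tempfile(fileext = ".txt")
  write_embeddings(tab, p)
  back <- read_embeddings(p, oov_seed = tab$oov_seed)
  for (tok in names(tab$vocab)) {
    expect_equal(back$vectors[back$vocab[[tok]], ],
                 tab$vectors[tab$vocab[[tok]], ], tolerance = 1e-12)
  }
})

test_that("degenerate corpora are rejected", {
  expect_error(train_atom_embeddings(list()), "empty corpus")
  expect_error(train_atom_embeddings(list(character(0))), "empty sentence")
})
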