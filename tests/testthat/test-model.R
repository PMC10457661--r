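test_that("default predictor dimensions are 768 / 256 / 1", {
  cfg <- cmms_config()
  set.seed(40)
  params <- cmms:::model_params_init(cfg)
  expect_equal(dim(params$pred1$W), c(768L, 256L))
  expect_equal(dim(params$pred2$W), c(256L, 1L))
  expect_equal(2L * cfg$d_g + cfg$d_s, 768L)
})

test_that("scores are sigmoid logits strictly inside (0, 1)", {
  set.seed(41)
  params <- list(pred1 = cmms:::linear_init(10L, 4L),
                 pred2 = cmms:::linear_init(4L, 1L))
  z <- rnorm(6); s <- rnorm(4)
  sc <- predict_score(z, s, params)
  expect_gt(sc, 0)
  expect_lt(sc, 1)
  # all-zero weights give exactly 0.5
  params0 <- list(pred1 = list(W = matrix(0, 10, 4), b = rep(0, 4)),
                  pred2 = list(W = matrix(0, 4, 1), b = 0))
  expect_equal(predict_score(z, s, params0), 0.5)
  expect_error(predict_score(rnorm(3), s, params), "width")
})

test_that("the joint loss composes exactly as L_C + lambda * L_CL", {
  set.seed(42)
  scores <- runif(8, 0.05, 0.95)
  labels <- sample(0:1, 8, replace = TRUE)
  l_cl <- 3.0
  r <- total_loss(scores, labels, l_cl, lambda = 0.1)
  expect_identical(r$total, r$classification + 0.1 * r$contrastive)
  r0 <- total_loss(scores, labels, l_cl, lambda = 0)
  expect_identical(r0$total, r0$classification)
  # lambda = 0.1, L_C = 2, L_CL = 3 -> 2.3
  p <- plogis(2)  # one sample engineered so that -log(p(y)) = known value
  r2 <- total_loss(p, 1, 3, lambda = 0.1)
  expect_equal(r2$total, -log(p) + 0.3, tolerance = 1e-12)
  expect_equal(total_loss(c(exp(-2)), c(1), 3.0, 0.1)$total, 2.3,
               tolerance = 1e-12)
})

test_that("cross-entropy decreases monotonically as the logit grows", {
  losses <- vapply(c(1, 5, 10), function(l) {
    total_loss(plogis(l), 1, 0, 0)$classification
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-4)
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_config(lambda = 0.3)
  set.seed(43)
  params <- cmms:::model_params_init(cfg)
  state <- list(gin = cmms:::gin_state_init(cfg$d_g, cfg$K))
  d <- synth_molecules(10, seed = 44)
  graphs <- lapply(d$smiles[1:4], smiles_to_graph)
  Zs <- lapply(d$smiles[1:4], function(s) {
    matrix(rnorm(length(tokenize_smiles(s)) * cfg$d1), ncol = cfg$d1)
  })
  items <- list(Zs = Zs, graphs = graphs, labels = c(1, 0, 1, 0),
                mask_vector = colMeans(graphs[[1]]$features))
  loss_at <- function(p) {
    withr::with_seed(99, cmms:::model_loss_grads(p, state, items, cfg,
                                                 training = TRUE)$loss)
  }
  out <- withr::with_seed(99, cmms:::model_loss_grads(params, state, items,
                                                      cfg, training = TRUE))
  paths <- list(c("gin", "layers", 1L, "lin1", "W"),
                c("gin", "layers", 2L, "bn", "gamma"),
                c("gin", "layers", 1L, "eps"),
                c("pred1", "W"),
                c("gru", "fwd", "Un"),
                c("gru", "bwd", "Wr"),
                c("att", "heads", 1L, "W1"),
                c("att", "fcs", "W"))
  assign_path <- function(tree, path, val) {
    if (length(path) == 0) return(val)
    tree[[path[[1]]]] <- assign_path(tree[[path[[1]]]], path[-1], val)
    tree
  }
  set.seed(45)
  for (path in paths) {
    pv <- params; gv <- out$grads
    for (k in path) { pv <- pv[[k]]; gv <- gv[[k]] }
    for (idx in sample(length(pv), min(2, length(pv)))) {
      eps <- 1e-5
      up <- pv; up[idx] <- up[idx] + eps
      dn <- pv; dn[idx] <- dn[idx] - eps
      num <- (loss_at(assign_path(params, path, up)) -
                loss_at(assign_path(params, path, dn))) / (2 * eps)
      expect_equal(gv[idx], num, tolerance = 1e-4,
                   info = paste(unlist(path), collapse = "$"))
    }
  }
})

test_that("training reduces the loss on separable data", {
  for (seed in 1:2) {
    d <- synth_molecules(240, noise = 0, seed = seed)
    cfg <- cmms_config(epochs = 6, batch_size = 48, seed = seed,
                       embed_epochs = 2)
    m <- cmms_fit(d, cfg)
    h <- tidy(m)
    expect_lt(h$loss[nrow(h)], h$loss[1])
  }
})

test_that("ablation variants build runnable models", {
  d <- synth_molecules(60, noise = 0, seed = 50)
  variants <- list(
    cmms_config(epochs = 1, batch_size = 16, seed = 1, embed_epochs = 1,
                use_sequence = FALSE),                    # graph-only
    cmms_config(epochs = 1, batch_size = 16, seed = 1, embed_epochs = 1,
                lambda = 0),                              # no contrastive
    cmms_config(epochs = 1, batch_size = 16, seed = 1, embed_epochs = 1,
                augment = "node_dropping", ratio = 0.2),
    cmms_config(epochs = 1, batch_size = 16, seed = 1, embed_epochs = 1,
                augment = "edge_perturbation"),
    cmms_config(epochs = 1, batch_size = 16, seed = 1, embed_epochs = 1,
                augment = "attribute_masking"))
  for (cfg in variants) {
    m <- cmms_fit(d, cfg)
    pr <- predict(m, d[1:10, ])
    expect_true(all(pr$score > 0 & pr$score < 1))
  }
})

test_that("single-class training data is rejected", {
  d <- synth_molecules(30, noise = 0, seed = 51)
  d$label <- 1L
  expect_error(cmms_fit(d, tiny_config()), "both classes")
})

test_that("models survive a checkpoint round trip", {
  sm <- small_model()
  p <- tempfile(fileext = ".ckpt")
  cmms_save(sm$model, p)
  back <- cmms_load(p)
  pr1 <- predict(sm$model, sm$test)
  pr2 <- predict(back, sm$test)
  expect_identical(pr1$score, pr2$score)
})
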