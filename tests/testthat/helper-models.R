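# Shared fitted models, trained once per test run and cached.

.model_cache <- new.env(parent = emptyenv())

# small-but-real model for explanation tests (fast to fit)
small_model <- function(seed = 2L) {
  key <- paste0("small", seed)
  if (is.null(.model_cache[[key]])) {
    d <- synth_molecules(200, noise = 0, seed = seed)
    cfg <- cmms_config(epochs = 6, batch_size = 32, seed = seed,
                       embed_epochs = 3)
    .model_cache[[key]] <- list(model = cmms_fit(d[1:160, ], cfg),
                                test = d[161:200, ])
  }
  .model_cache[[key]]
}

# the synthetic-recovery study: n = 2000, 5% label noise, 30 epochs,
# batch 64, stratified 80/20 holdout; cached per seed
recovery_run <- function(seed) {
  key <- paste0("recovery", seed)
  if (is.null(.model_cache[[key]])) {
    d <- synth_molecules(2000, noise = 0.05, seed = seed)
    te_idx <- withr::with_seed(seed, sample.int(nrow(d), 400))
    tr <- d[-te_idx, ]
    te <- d[te_idx, ]
    cfg <- cmms_config(epochs = 30, batch_size = 64, seed = seed)
    model <- cmms_fit(tr, cfg)
    preds <- predict(model, te)
    .model_cache[[key]] <- list(model = model, test = te, preds = preds)
  }
  .model_cache[[key]]
}

tiny_config <- function(...) {
  cmms_config(d1 = 8, d2 = 10, d_s = 7, d_g = 6, d_att = 5, K = 2,
              heads = 2, hidden_pred = 6, batch_size = 4, epochs = 2,
              embed_epochs = 1, ...)
}
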