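#' Fit the cross-modality stability model
#'
#' Trains the fused sequence/structure classifier on a labelled molecule
#' table. Unless an embedding table is supplied, skip-gram token embeddings
#' are pretrained on the training SMILES themselves. Optimization is Adam on
#' the joint loss `L_C + lambda * L_CL`; each epoch reshuffles molecules,
#' groups them into length-bucketed minibatches and resamples the contrastive
#' substructure views. The whole run is reproducible from `config$seed`.
#'
#' @param data Tibble/data frame with columns `smiles` and `label` (binary,
#'   1 = stable); an `id` column is added if missing. Both classes must be
#'   present.
#' @param config A [cmms_config()].
#' @param embeddings Optional pretrained [train_atom_embeddings()] table;
#'   default pretrains on `data$smiles`.
#' @param validation Optional held-out tibble (same columns) evaluated after
#'   every epoch.
#' @param verbose Print per-epoch progress.
#' @return An object of class `cmms_model` with elements `params`, `state`,
#'   `config`, `embeddings`, `history` (tibble of per-epoch losses and
#'   metrics) and `mask_vector`. Methods: [predict.cmms_model()],
#'   [tidy.cmms_model()], [glance.cmms_model()], [autoplot.cmms_model()].
#' @export
cmms_fit <- function(data, config = cmms_config(), embeddings = NULL,
                     validation = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data), all(c("smiles", "label") %in% names(data)))
  if (!all(data$label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(data$label)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (!"id" %in% names(data)) data$id <- sprintf("mol%05d", seq_len(nrow(data)))

  withr_seed(config$seed, {
    prep <- prepare_molecules(data, config, embeddings)
    embeddings <- prep$embeddings
    mask_vector <- colMeans(do.call(rbind, lapply(prep$graphs,
                                                  function(g) g$features)))
    params <- model_params_init(config)
    state <- list(gin = gin_state_init(config$d_g, config$K))
    opt <- adam_init(params)
    n <- nrow(data)
    y <- as.numeric(data$label)
    hist <- vector("list", config$epochs)

    for (ep in seq_len(config$epochs)) {
      idx <- bucketed_batches(prep$lengths, config$batch_size)
      ep_loss <- 0; ep_lc <- 0; ep_lcl <- 0; n_b <- 0L
      for (b in idx) {
        items <- list(Zs = prep$Zs[b], graphs = prep$graphs[b],
                      labels = y[b], mask_vector = mask_vector)
        out <- model_loss_grads(params, state, items, config, training = TRUE)
        state <- out$state
        st <- adam_step(params, out$grads, opt, config$lr)
        params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + out$loss
        ep_lc <- ep_lc + out$l_c
        ep_lcl <- ep_lcl + out$l_cl
        n_b <- n_b + 1L
      }
      row <- tibble::tibble(epoch = ep, loss = ep_loss / n,
                            loss_class = ep_lc / n, loss_contr = ep_lcl / n_b)
      if (!is.null(validation)) {
        mdl <- new_cmms_model(params, state, config, embeddings, NULL,
                              mask_vector)
        pr <- stats::predict(mdl, validation)
        mt <- evaluate_predictions(dplyr::mutate(pr,
                                                 label = validation$label))
        row$val_auc <- mt$auc
        row$val_accuracy <- mt$accuracy
      }
      hist[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f (class %.4f, contr %.4f)%s",
                        ep, row$loss, row$loss_class, row$loss_contr,
                        if (!is.null(validation))
                          sprintf("  val AUC %.3f", row$val_auc) else ""))
      }
    }
    new_cmms_model(params, state, config, embeddings,
                   dplyr::bind_rows(hist), mask_vector)
  })
}

new_cmms_model <- function(params, state, config, embeddings, history,
                           mask_vector) {
  structure(list(params = params, state = state, config = config,
                 embeddings = embeddings, history = history,
                 mask_vector = mask_vector),
            class = "cmms_model")
}

# tokenize, embed and parse every molecule once
prepare_molecules <- function(data, config, embeddings) {
  tokens <- lapply(data$smiles, tokenize_one)
  if (is.null(embeddings)) {
    embeddings <- train_atom_embeddings(tokens, d1 = config$d1,
                                        window = config$embed_window,
                                        epochs = config$embed_epochs,
                                        seed = config$seed)
  }
  graphs <- lapply(seq_len(nrow(data)), function(i) {
    g <- smiles_to_graph(data$smiles[i], id = data$id[i])
    g$adj <- adjacency_list(g)   # reused by every augmentation draw
    g
  })
  Zs <- if (config$use_sequence) {
    lapply(tokens, embed_sequence, table = embeddings)
  } else {
    lapply(tokens, function(t) matrix(0, 1, 1))
  }
  list(tokens = tokens, graphs = graphs, Zs = Zs, embeddings = embeddings,
       lengths = lengths(tokens))
}

# shuffle, order by sequence length within the shuffle, cut into batches of
# near-equal length, then shuffle the batch order (drop no molecules)
bucketed_batches <- function(lens, batch_size) {
  n <- length(lens)
  perm <- sample.int(n)
  perm <- perm[order(lens[perm])]
  nb <- ceiling(n / batch_size)
  batches <- split(perm, rep(seq_len(nb), each = batch_size, length.out = n))
  batches[sample.int(nb)]
}

#' Predict stability scores for new molecules
#'
#' @param object A fitted `cmms_model`.
#' @param newdata Tibble/data frame with a `smiles` column (an `id` column is
#'   added if missing).
#' @param batch_size Molecules scored per forward pass.
#' @param ... Unused.
#' @return Tibble with `id`, `smiles`, `score` (probability of being stable,
#'   strictly in (0, 1)) and `class` (score thresholded at 0.5).
#' @export
predict.cmms_model <- function(object, newdata, batch_size = 256L, ...) {
  stopifnot(is.data.frame(newdata), "smiles" %in% names(newdata))
  if (!"id" %in% names(newdata)) {
    newdata$id <- sprintf("mol%05d", seq_len(nrow(newdata)))
  }
  config <- object$config
  tokens <- lapply(newdata$smiles, tokenize_one)
  graphs <- lapply(seq_len(nrow(newdata)), function(i) {
    smiles_to_graph(newdata$smiles[i], id = newdata$id[i])
  })
  Zs <- if (config$use_sequence) {
    lapply(tokens, embed_sequence, table = object$embeddings)
  } else {
    lapply(tokens, function(t) matrix(0, 1, 1))
  }
  n <- nrow(newdata)
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    b <- start:min(start + batch_size - 1L, n)
    items <- list(Zs = Zs[b], graphs = graphs[b], labels = rep(0, length(b)),
                  mask_vector = object$mask_vector)
    fwd <- model_fwd(object$params, object$state, items, config,
                     training = FALSE, with_contrastive = FALSE)
    scores[b] <- sigmoid(fwd$logits)
  }
  tibble::tibble(id = newdata$id, smiles = newdata$smiles, score = scores,
                 class = as.integer(scores >= 0.5))
}

#' @export
print.cmms_model <- function(x, ...) {
  np <- length(tree_flatten(x$params))
  cat(sprintf(paste0("<cmms_model> cross-modality stability classifier\n",
                     "  %d parameters; %s sequence branch; GIN K=%d; ",
                     "lambda=%.3g; augment=%s\n"),
              np, if (x$config$use_sequence) "with" else "without",
              x$config$K, x$config$lambda, x$config$augment))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                nrow(x$history), last$loss))
  }
  invisible(x)
}

#' Save a fitted model to a single-file checkpoint
#'
#' The checkpoint holds weights, configuration, embedding table, batch-norm
#' state and a schema version.
#'
#' @param model A `cmms_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
cmms_save <- function(model, path) {
  stopifnot(inherits(model, "cmms_model"))
  payload <- unclass(model)
  payload$schema_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint written by [cmms_save()]
#'
#' @param path Checkpoint file.
#' @return A `cmms_model`.
#' @export
cmms_load <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$schema_version) || payload$schema_version != 1L) {
    stop("unrecognised checkpoint schema", call. = FALSE)
  }
  payload$schema_version <- NULL
  structure(payload, class = "cmms_model")
}
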