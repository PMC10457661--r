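# The fused stability predictor: sequence representation s_i (attention
# BiGRU over pretrained token embeddings) and structure representation z_i
# (2-layer GIN, max+mean pooled) are concatenated and classified by a fully
# connected head (768 -> 256 -> 1 logit). Training minimizes
#   L = L_C + lambda * L_CL
# where L_C is the summed binary cross-entropy over the minibatch and L_CL
# the inter-view contrastive loss between each molecule's graph and a sampled
# substructure of it. Optimization is Adam; all randomness (shuffling,
# augmentation, initialization) flows from the configured seed.

#' Model configuration
#'
#' Collects every tunable of the cross-modality model with its default:
#' embedding width `d1 = 100`, BiGRU output width `d2 = 200` (hidden 100 per
#' direction), attention heads `heads = 4` with scoring width `d_att = 64`,
#' sequence representation `d_s = 256`, GIN width `d_g = 256` with `K = 2`
#' layers (structure representation `d3 = 512`), predictor widths 768/256/1,
#' contrastive temperature `tau = 0.2`, augmentation `substructure` at
#' `ratio = 0.4`, loss weight `lambda = 0.1`, Adam with `lr = 5e-4`,
#' `epochs = 200`, `batch_size = 128`.
#'
#' @param d1,d2,d_s,d_g,d_att Layer widths (see above); `d2` must be even.
#' @param K Number of GIN layers.
#' @param heads Number of attention heads.
#' @param hidden_pred Predictor hidden width.
#' @param tau Contrastive temperature.
#' @param lambda Weight of the contrastive term (0 disables it, the "without
#'   graph contrastive learning" ablation).
#' @param augment Augmentation scheme for the contrastive view.
#' @param ratio Augmentation ratio.
#' @param epochs,lr,batch_size Optimization settings.
#' @param use_sequence Set `FALSE` for the graph-only ablation (structure
#'   encoder and predictor only).
#' @param embed_window,embed_epochs Skip-gram pretraining settings.
#' @param seed Integer seed for the whole pipeline.
#' @return A list of class `cmms_config`.
#' @export
cmms_config <- function(d1 = 100L, d2 = 200L, d_s = 256L, d_g = 256L,
                        d_att = 64L, K = 2L, heads = 4L, hidden_pred = 256L,
                        tau = 0.2, lambda = 0.1,
                        augment = c("substructure", "node_dropping",
                                    "edge_perturbation", "attribute_masking"),
                        ratio = 0.4, epochs = 200L, lr = 5e-4,
                        batch_size = 128L, use_sequence = TRUE,
                        embed_window = 5L, embed_epochs = 10L, seed = 1L) {
  stopifnot(d2 %% 2L == 0L, K >= 1L, heads >= 1L, lambda >= 0, tau > 0,
            ratio > 0, ratio <= 1, epochs >= 1L, batch_size >= 2L)
  structure(list(d1 = as.integer(d1), d2 = as.integer(d2),
                 d_s = as.integer(d_s), d_g = as.integer(d_g),
                 d_att = as.integer(d_att), K = as.integer(K),
                 heads = as.integer(heads),
                 hidden_pred = as.integer(hidden_pred), tau = tau,
                 lambda = lambda, augment = match.arg(augment), ratio = ratio,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 use_sequence = isTRUE(use_sequence),
                 embed_window = as.integer(embed_window),
                 embed_epochs = as.integer(embed_epochs),
                 seed = as.integer(seed)),
            class = "cmms_config")
}

pred_input_width <- function(config) {
  2L * config$d_g + if (config$use_sequence) config$d_s else 0L
}

model_params_init <- function(config) {
  p <- list(
    gin = gin_init(84L, config$d_g, config$K),
    pred1 = linear_init(pred_input_width(config), config$hidden_pred),
    pred2 = linear_init(config$hidden_pred, 1L)
  )
  if (config$use_sequence) {
    p$gru <- bigru_init(config$d1, config$d2 %/% 2L)
    p$att <- attention_init(config$d2, config$d_att, config$heads, config$d_s)
  }
  p
}

# pad a list of embedding matrices into the flat time-major layout used by
# the BiGRU: block t of Xbig holds position t of every molecule
pad_sequences <- function(Zs) {
  lens <- vapply(Zs, nrow, integer(1))
  m <- max(lens)
  B <- length(Zs)
  d <- ncol(Zs[[1]])
  mask <- matrix(0, B, m)
  Xbig <- matrix(0, m * B, d)
  for (i in seq_len(B)) {
    li <- lens[i]
    mask[i, seq_len(li)] <- 1
    Xbig[(seq_len(li) - 1L) * B + i, ] <- Zs[[i]]
  }
  list(Xbig = Xbig, mask = mask, lengths = lens, B = B, m = m)
}

# forward pass over one prepared minibatch
# items: list with Zs (embedding matrices), graphs, labels
model_fwd <- function(params, state, items, config, training,
                      with_contrastive = TRUE) {
  B <- length(items$graphs)
  contrast <- with_contrastive && config$lambda > 0 && B >= 2L
  # originals and (when contrasting) their augmented views share one
  # block-diagonal pass through the GIN, so both views are normalized with
  # the same batch statistics
  gset <- items$graphs
  if (contrast) {
    aug <- lapply(items$graphs, augment_graph, method = config$augment,
                  ratio = config$ratio, mask_vector = items$mask_vector)
    gset <- c(gset, aug)
  }
  bg <- batch_graphs(gset)
  gfwd <- gin_fwd(bg, params$gin, state$gin, training)
  state$gin <- gfwd$state
  z <- gfwd$p[seq_len(B), , drop = FALSE]
  zhat <- NULL; ctr <- NULL
  if (contrast) {
    zhat <- gfwd$p[B + seq_len(B), , drop = FALSE]
    ctr <- contrastive_fwd(rbind(z, zhat), config$tau)
  }

  sfwd <- NULL; pad <- NULL; bfwd <- NULL
  if (config$use_sequence) {
    pad <- pad_sequences(items$Zs)
    bfwd <- bigru_fwd(pad$Xbig, pad$mask, params$gru, pad$B, pad$m)
    sfwd <- attention_fwd(bfwd$H, pad$mask, params$att, pad$B, pad$m)
    x <- cbind(z, sfwd$s)
  } else {
    x <- z
  }
  l1 <- linear_fwd(x, params$pred1)
  h1 <- pmax(l1$out, 0)
  l2 <- linear_fwd(h1, params$pred2)
  logits <- as.numeric(l2$out)

  list(logits = logits, z = z, s = if (!is.null(sfwd)) sfwd$s,
       state = state,
       cache = list(bg = bg, gfwd = gfwd, sfwd = sfwd, pad = pad,
                    bfwd = bfwd, x = x, h1 = h1, l1_pre = l1$out,
                    ctr = ctr, B = B))
}

# total loss and parameter gradients for one minibatch
model_loss_grads <- function(params, state, items, config, training = TRUE) {
  fwd <- model_fwd(params, state, items, config, training)
  y <- items$labels
  logits <- fwd$logits
  # summed binary cross-entropy, numerically stable form
  l_c <- sum(log1pexp(logits) - y * logits)
  l_cl <- if (!is.null(fwd$cache$ctr)) fwd$cache$ctr$loss else 0
  loss <- l_c + config$lambda * l_cl

  cache <- fwd$cache
  grads <- list()

  dlogit <- matrix(sigmoid(logits) - y, ncol = 1)
  l2b <- linear_bwd(list(x = cache$h1), dlogit, params$pred2)
  grads$pred2 <- l2b$grads
  dh1 <- l2b$dx * (cache$l1_pre > 0)
  l1b <- linear_bwd(list(x = cache$x), dh1, params$pred1)
  grads$pred1 <- l1b$grads
  dx <- l1b$dx

  dz <- dx[, seq_len(2L * config$d_g), drop = FALSE]
  if (!is.null(cache$ctr)) {
    dreps <- contrastive_bwd(cache$ctr$cache) * config$lambda
    dp <- dreps
    dp[seq_len(cache$B), ] <- dp[seq_len(cache$B), , drop = FALSE] + dz
  } else {
    dp <- dz
  }
  grads$gin <- gin_bwd(cache$bg, params$gin, cache$gfwd, dp)$grads

  if (config$use_sequence) {
    ds <- dx[, 2L * config$d_g + seq_len(config$d_s), drop = FALSE]
    atb <- attention_bwd(cache$sfwd$cache, ds, params$att)
    grads$att <- atb$grads
    grads$gru <- bigru_bwd(cache$bfwd$cache, atb$dH, params$gru)
  }

  list(loss = loss, l_c = l_c, l_cl = l_cl, grads = grads,
       state = fwd$state, logits = logits)
}

#' Combine classification and contrastive losses
#'
#' `L = L_C + lambda * L_CL`, where `L_C` is the summed binary cross-entropy
#' of the scores against the labels and `L_CL` a contrastive loss value.
#' Returned alongside its two components; with `lambda = 0` the total equals
#' the classification term exactly.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels Binary labels.
#' @param l_cl Contrastive loss value.
#' @param lambda Trade-off weight.
#' @return Named list `total`, `classification`, `contrastive`.
#' @export
total_loss <- function(scores, labels, l_cl, lambda = 0.1) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            lambda >= 0)
  l_c <- -sum(labels * log(scores) + (1 - labels) * log(1 - scores))
  list(total = l_c + lambda * l_cl, classification = l_c, contrastive = l_cl)
}

#' Score a molecule from its two representations
#'
#' Concatenates a structure representation `z` and a sequence representation
#' `s` and applies the fully connected predictor; the score is the sigmoid of
#' the final logit and always lies strictly inside (0, 1).
#'
#' @param z Structure representation vector.
#' @param s Sequence representation vector (omit for graph-only models).
#' @param params Model parameter list (`$pred1`, `$pred2`).
#' @return Probability that the molecule is metabolically stable.
#' @export
predict_score <- function(z, s = NULL, params) {
  x <- matrix(c(z, s), nrow = 1)
  if (ncol(x) != nrow(params$pred1$W)) {
    stop(sprintf("representation width %d does not match predictor input %d",
                 ncol(x), nrow(params$pred1$W)), call. = FALSE)
  }
  h1 <- pmax(linear_fwd(x, params$pred1)$out, 0)
  sigmoid(as.numeric(linear_fwd(h1, params$pred2)$out))
}
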