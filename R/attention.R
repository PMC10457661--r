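# Multihead additive attention pooling over BiGRU hidden states, followed by
# a fully connected map to the molecule sequence representation. Per head k:
#   e_t = tanh(h_t W1_k + b1_k) w2_k        (scalar score per position)
#   alpha = softmax over valid positions
#   c_k = sum_t alpha_t h_t
# Head contexts are averaged and passed through FCs (linear + ReLU) to give
# the sequence representation s_i. Hidden states arrive in the flat
# time-major layout of the BiGRU (block t = rows (t-1)*B+1 .. t*B).

attention_init <- function(d2, d_att, heads, d_s) {
  list(heads = lapply(seq_len(heads), function(k) {
    list(W1 = glorot(d2, d_att), b1 = rep(0, d_att),
         w2 = matrix(stats::runif(d_att, -0.1, 0.1), d_att, 1))
  }),
  fcs = linear_init(d2, d_s))
}

# Hbig: (m*B) x d2; mask: B x m
attention_fwd <- function(Hbig, mask, params, B, m) {
  d2 <- ncol(Hbig)
  grp <- rep(seq_len(B), m)          # molecule index of each flat row
  n_heads <- length(params$heads)
  d_att <- ncol(params$heads[[1]]$W1)
  # all heads' scoring maps run as one stacked matmul
  W1_all <- do.call(cbind, lapply(params$heads, `[[`, "W1"))
  b1_all <- unlist(lapply(params$heads, `[[`, "b1"))
  u_all <- tanh(Hbig %*% W1_all + rep(b1_all, each = nrow(Hbig)))
  alphas <- vector("list", n_heads)
  hcaches <- vector("list", n_heads)
  cmean <- matrix(0, B, d2)
  for (k in seq_len(n_heads)) {
    p <- params$heads[[k]]
    u <- u_all[, (k - 1L) * d_att + seq_len(d_att), drop = FALSE]
    e <- matrix(u %*% p$w2, B, m)    # column t <- block t (column-major)
    a <- masked_softmax(e, mask)
    ctx <- rowsum(as.numeric(a) * Hbig, grp)
    cmean <- cmean + ctx
    alphas[[k]] <- a
    hcaches[[k]] <- list(u = u, a = a)
  }
  cmean <- cmean / n_heads
  fc <- linear_fwd(cmean, params$fcs)
  s <- pmax(fc$out, 0)
  list(s = s, alphas = alphas,
       cache = list(Hbig = Hbig, hcaches = hcaches, cmean = cmean,
                    fc_pre = fc$out, mask = mask, m = m, B = B, d2 = d2,
                    grp = grp))
}

attention_bwd <- function(cache, ds, params) {
  m <- cache$m; B <- cache$B
  n_heads <- length(params$heads)
  d_att <- ncol(params$heads[[1]]$W1)
  dfc <- ds * (cache$fc_pre > 0)
  lb <- linear_bwd(list(x = cache$cmean), dfc, params$fcs)
  dctx <- lb$dx / n_heads            # same for every head
  dctx_big <- dctx[cache$grp, , drop = FALSE]
  # d(context)/d(alpha_t) is also head-independent
  da <- matrix(rowSums(dctx_big * cache$Hbig), B, m)
  a_sum <- 0
  DU <- matrix(0, nrow(cache$Hbig), n_heads * d_att)
  gheads <- vector("list", n_heads)
  for (k in seq_len(n_heads)) {
    p <- params$heads[[k]]
    hc <- cache$hcaches[[k]]
    a_sum <- a_sum + as.numeric(hc$a)
    # softmax backward (rows of the B x m weight matrix)
    de <- hc$a * (da - rowSums(da * hc$a))
    de_flat <- matrix(as.numeric(de), ncol = 1)
    du <- (de_flat %*% t(p$w2)) * (1 - hc$u^2)
    DU[, (k - 1L) * d_att + seq_len(d_att)] <- du
    gheads[[k]] <- list(W1 = NULL, b1 = colSums(du),
                        w2 = crossprod(hc$u, de_flat))
  }
  dH <- a_sum * dctx_big
  W1_all <- do.call(cbind, lapply(params$heads, `[[`, "W1"))
  dH <- dH + DU %*% t(W1_all)
  gW1_all <- crossprod(cache$Hbig, DU)
  for (k in seq_len(n_heads)) {
    gheads[[k]]$W1 <- gW1_all[, (k - 1L) * d_att + seq_len(d_att),
                              drop = FALSE]
  }
  list(grads = list(heads = gheads, fcs = lb$grads), dH = dH)
}

#' Attention-pool a hidden-state matrix into a molecule representation
#'
#' Applies each attention head's scoring map to every position, softmax-
#' normalizes over positions (weights are nonnegative and sum to one per
#' head), averages the heads' attention-weighted sums, and maps the result
#' through the fully connected output layer.
#'
#' @param H Numeric matrix m x d2 of per-token hidden states.
#' @param params Attention parameter list (see [cmms_fit()]); create a fresh
#'   one with `cmms:::attention_init(d2, d_att, heads, d_s)`.
#' @return List with `attention` (heads x m matrix of weights, each row
#'   summing to 1) and `seq_rep` (the pooled representation).
#' @export
attention_pool <- function(H, params) {
  H <- as.matrix(H)
  m <- nrow(H)
  out <- attention_fwd(H, matrix(1, 1, m), params, B = 1L, m = m)
  att <- do.call(rbind, lapply(out$alphas, function(a) a[1, ]))
  list(attention = att, seq_rep = out$s[1, ])
}
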