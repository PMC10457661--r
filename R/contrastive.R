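# Temperature-scaled inter-view contrastive loss (NT-Xent). A batch stacks Q
# original-graph representations z_i on top of their Q subgraph
# representations z^_i (rows i and i+Q are the positive pair). For anchor i
# with positive p(i):
#
#   l(i) = -log( exp(cos(z_i, z_p)/tau) / sum_{k != i} exp(cos(z_i, z_k)/tau) )
#
# with the denominator running over all other 2Q-1 rows (the positive
# included), and the total loss the mean of l over all 2Q anchors, i.e.
# (1/2Q) sum_i [l(z_i, z^_i) + l(z^_i, z_i)].

#' Contrastive loss of one anchor against its batch
#'
#' @param reps Numeric matrix 2Q x d; rows `i` and `i + Q` form a positive
#'   pair. All rows must be nonzero.
#' @param i Anchor row index (1-based, in 1..2Q).
#' @param tau Temperature (default 0.2).
#' @return The anchor's loss (scalar).
#' @export
ntxent_pair_loss <- function(reps, i, tau = 0.2) {
  reps <- as.matrix(reps)
  n2q <- nrow(reps)
  if (n2q < 4L || n2q %% 2L != 0L) {
    stop("reps must stack Q originals over Q subgraphs (2Q >= 4 rows)",
         call. = FALSE)
  }
  nrm <- sqrt(rowSums(reps^2))
  if (any(nrm < 1e-12)) stop("zero-norm representation row", call. = FALSE)
  q <- n2q %/% 2L
  pos <- if (i <= q) i + q else i - q
  zn <- reps / nrm
  sims <- as.numeric(zn %*% zn[i, ])
  logits <- sims / tau
  denom_idx <- setdiff(seq_len(n2q), i)
  mx <- max(logits[denom_idx])
  -(logits[pos] - (mx + log(sum(exp(logits[denom_idx] - mx)))))
}

#' Inter-view contrastive loss of a batch
#'
#' Mean of [ntxent_pair_loss()] over all 2Q anchors: each molecule's graph
#' representation is pulled toward its subgraph representation and pushed
#' away from the other 2Q - 2 rows.
#'
#' @inheritParams ntxent_pair_loss
#' @return Scalar loss.
#' @export
contrastive_loss <- function(reps, tau = 0.2) {
  out <- contrastive_fwd(as.matrix(reps), tau)
  out$loss
}

# forward with cache for backprop
contrastive_fwd <- function(reps, tau) {
  n2q <- nrow(reps)
  if (n2q < 4L || n2q %% 2L != 0L) {
    stop("reps must stack Q originals over Q subgraphs (2Q >= 4 rows)",
         call. = FALSE)
  }
  nrm <- sqrt(rowSums(reps^2))
  if (any(nrm < 1e-12)) stop("zero-norm representation row", call. = FALSE)
  q <- n2q %/% 2L
  zn <- reps / nrm
  S <- tcrossprod(zn) / tau
  diag(S) <- -Inf                      # k != i: anchor excluded from denom
  mx <- apply(S, 1, max)
  P <- exp(S - mx)                     # row-stochastic after normalization
  rs <- rowSums(P)
  pos <- c((q + 1L):n2q, 1L:q)
  pos_logit <- S[cbind(seq_len(n2q), pos)]
  loss <- mean(-(pos_logit - (mx + log(rs))))
  list(loss = loss,
       cache = list(zn = zn, nrm = nrm, P = P / rs, pos = pos, tau = tau,
                    n2q = n2q))
}

# gradient of the batch loss w.r.t. the (unnormalized) representation rows
contrastive_bwd <- function(cache) {
  n2q <- cache$n2q
  tau <- cache$tau
  dS <- cache$P / (n2q * tau)          # softmax term
  dS[cbind(seq_len(n2q), cache$pos)] <-
    dS[cbind(seq_len(n2q), cache$pos)] - 1 / (n2q * tau)
  diag(dS) <- 0
  dzn <- (dS + t(dS)) %*% cache$zn     # S = zn zn^T
  # through row normalization: dz = (dzn - zn * <zn, dzn>) / ||z||
  inner <- rowSums(dzn * cache$zn)
  (dzn - cache$zn * inner) / cache$nrm
}
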