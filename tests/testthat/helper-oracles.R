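# Independent oracles used across test files.

# regex-free left-to-right SMILES scanner that longest-matches element
# symbols; independent of the package tokenizer
scanner_oracle <- function(smiles) {
  two_letter <- c("Cl", "Br")
  singles <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s",
               "-", "=", "#", ":", "/", "\\", "(", ")", ".",
               as.character(0:9))
  out <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- i
      while (j <= n && substr(smiles, j, j) != "]") j <- j + 1L
      out <- c(out, substr(smiles, i, j))
      i <- j + 1L
    } else if (i < n && substr(smiles, i, i + 1L) %in% two_letter) {
      out <- c(out, substr(smiles, i, i + 1L))
      i <- i + 2L
    } else if (ch %in% singles) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop("oracle: unknown char ", ch)
    }
  }
  out
}

# per-node loop implementation of one GIN layer (definition, not the
# package's batched path). mlp = NULL applies no transformation.
gin_layer_oracle <- function(features, edges, epsilon, mlp = NULL,
                             state = NULL) {
  n <- nrow(features)
  out <- matrix(0, n, if (is.null(mlp)) ncol(features)
                      else ncol(mlp$lin2$W))
  for (v in seq_len(n)) {
    agg <- (1 + epsilon) * features[v, ]
    if (nrow(edges) > 0) {
      for (e in seq_len(nrow(edges))) {
        if (edges[e, 1] == v) agg <- agg + features[edges[e, 2], ]
        if (edges[e, 2] == v) agg <- agg + features[edges[e, 1], ]
      }
    }
    if (is.null(mlp)) {
      out[v, ] <- agg
    } else {
      a1 <- as.numeric(agg %*% mlp$lin1$W)
      mu <- state$mean; vv <- state$var
      xhat <- (a1 - mu) / sqrt(vv + state$eps)
      bn <- xhat * mlp$bn$gamma + mlp$bn$beta
      r <- pmax(bn, 0)
      out[v, ] <- as.numeric(r %*% mlp$lin2$W) + mlp$lin2$b
    }
  }
  out
}

# direct per-timestep GRU recurrence on one sequence (no batching, no masks)
gru_oracle <- function(Z, p) {
  m <- nrow(Z)
  h <- rep(0, ncol(p$Ur))
  H <- matrix(0, m, ncol(p$Ur))
  for (t in seq_len(m)) {
    x <- Z[t, ]
    r <- 1 / (1 + exp(-(x %*% p$Wr + h %*% p$Ur + p$br)))
    u <- 1 / (1 + exp(-(x %*% p$Wu + h %*% p$Uu + p$bu)))
    nn <- tanh(x %*% p$Wn + p$bn + r * (h %*% p$Un + p$bhn))
    h <- as.numeric((1 - u) * nn + u * h)
    H[t, ] <- h
  }
  H
}

# naive O((2Q)^2) double-loop contrastive loss
contrastive_oracle <- function(reps, tau = 0.2) {
  n <- nrow(reps)
  q <- n / 2
  zn <- reps / sqrt(rowSums(reps^2))
  tot <- 0
  for (i in seq_len(n)) {
    pos <- if (i <= q) i + q else i - q
    num <- exp(sum(zn[i, ] * zn[pos, ]) / tau)
    den <- 0
    for (k in setdiff(seq_len(n), i)) {
      den <- den + exp(sum(zn[i, ] * zn[k, ]) / tau)
    }
    tot <- tot - log(num / den)
  }
  tot / n
}

# all-pairs AUC with half credit for ties
auc_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
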