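# Numerical building blocks for the encoders: parameter trees, Glorot
# initialization, Adam, batch normalization with running statistics, and a
# numerically safe sigmoid/softmax. All forward functions return caches that
# their backward counterparts consume; backward functions return gradients of
# the same shape as the parameters (verified against central finite
# differences in the test suite).

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

linear_init <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = rep(0, n_out))
}

linear_fwd <- function(x, p) {
  list(out = x %*% p$W + rep(p$b, each = nrow(x)), x = x)
}

linear_bwd <- function(cache, dout, p) {
  list(grads = list(W = crossprod(cache$x, dout), b = colSums(dout)),
       dx = dout %*% t(p$W))
}

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d))
}

bn_state_init <- function(d) {
  list(mean = rep(0, d), var = rep(1, d), momentum = 0.1, eps = 1e-5)
}

# batch normalization over rows; training mode uses batch statistics and
# returns an updated running-state, eval mode uses the running statistics
bn_fwd <- function(x, p, state, training) {
  n <- nrow(x)
  if (training && n > 1) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc^2)
    state$mean <- (1 - state$momentum) * state$mean + state$momentum * mu
    state$var <- (1 - state$momentum) * state$var +
      state$momentum * v * n / max(n - 1, 1)
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - rep(mu, each = n)
  }
  inv_sd <- 1 / sqrt(v + state$eps)
  out <- xc * rep(p$gamma * inv_sd, each = n) + rep(p$beta, each = n)
  list(out = out, state = state,
       cache = list(inv_sd = inv_sd, xc = xc, n = n,
                    batch_stats = training && n > 1))
}

bn_bwd <- function(cache, dout, p) {
  n <- cache$n
  dxc <- dout * cache$xc               # reused for the reductions below
  dgamma <- colSums(dxc) * cache$inv_sd
  dbeta <- colSums(dout)
  gi <- p$gamma * cache$inv_sd
  if (cache$batch_stats) {
    # dx via the standard batch-statistics chain rule
    cm1 <- colMeans(dout)
    cm2 <- colMeans(dxc) * cache$inv_sd^2
    dx <- (dout - rep(cm1, each = n) - cache$xc * rep(cm2, each = n)) *
      rep(gi, each = n)
  } else {
    dx <- dout * rep(gi, each = n)
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
}

# softmax over the columns of a B x m score matrix with a {0,1} validity
# mask; masked positions get zero weight
masked_softmax <- function(scores, mask) {
  s <- ifelse(mask > 0, scores, -Inf)
  mx <- apply(s, 1, max)
  e <- exp(s - mx) * mask
  e / pmax(rowSums(e), .Machine$double.eps)
}

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i]) && nm[i] %in% names(b)) {
        b[[nm[i]]]
      } else {
        b[[i]]
      }
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

# flatten leaves into one numeric vector (fixed traversal order)
tree_flatten <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_flatten), use.names = FALSE)
  else as.numeric(tree)
}

# ---- Adam ----------------------------------------------------------------

# rebuild a parameter tree from a flat vector using `skeleton` for shapes
tree_unflatten <- function(flat, skeleton, pos = 1L) {
  if (is.list(skeleton)) {
    out <- vector("list", length(skeleton))
    names(out) <- names(skeleton)
    for (i in seq_along(skeleton)) {
      r <- tree_unflatten(flat, skeleton[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    list(value = out, pos = pos)
  } else {
    k <- length(skeleton)
    v <- flat[pos:(pos + k - 1L)]
    if (is.matrix(skeleton)) dim(v) <- dim(skeleton)
    list(value = v, pos = pos + k)
  }
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# one recursive walk updating parameters and both moment trees together;
# gradient subtrees are matched to parameter subtrees by name
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        gi <- if (!is.null(nm) && nzchar(nm[i]) && nm[i] %in% names(g)) {
          g[[nm[i]]]
        } else {
          g[[i]]
        }
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        p[[i]] <- r[[1L]]; m[[i]] <- r[[2L]]; v[[i]] <- r[[3L]]
      }
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
    list(p, m, v)
  }
  r <- rec(params, grads, opt$m, opt$v)
  opt$m <- r[[2L]]
  opt$v <- r[[3L]]
  list(params = r[[1L]], opt = opt)
}
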