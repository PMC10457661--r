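# Graph isomorphism network over molecular graphs. Layer k updates every
# node v as MLP((1 + eps_k) * h_v + sum of neighbor states), where the MLP is
# linear -> batch norm -> ReLU -> linear. A molecule representation is the
# concatenation of global max- and mean-pooling over the final node states.
# Minibatches are encoded as one block-diagonal graph: node features stacked,
# edges offset, and a node -> graph index used for pooling.

gin_layer_init <- function(d_in, d_out) {
  # no bias on the first linear: batch norm absorbs any shift
  list(lin1 = list(W = glorot(d_in, d_out)), bn = bn_init(d_out),
       lin2 = linear_init(d_out, d_out), eps = 0)
}

gin_init <- function(d_in, d_g, K) {
  list(layers = lapply(seq_len(K), function(k) {
    gin_layer_init(if (k == 1) d_in else d_g, d_g)
  }))
}

gin_state_init <- function(d_g, K) {
  list(layers = lapply(seq_len(K), function(k) bn_state_init(d_g)))
}

# batch graph container: X (N x d), src/dst (directed edge endpoints, both
# directions of every undirected bond), graph (node -> graph index),
# n_graphs, sizes
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$features))
  src <- integer(0); dst <- integer(0)
  el <- lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0L) return(NULL)
    cbind(c(e[, 1], e[, 2]) + offs[i], c(e[, 2], e[, 1]) + offs[i])
  })
  el <- do.call(rbind, el)
  if (is.null(el)) el <- matrix(integer(0), 0, 2)
  n <- sum(ns)
  A <- Matrix::sparseMatrix(i = el[, 2], j = el[, 1], x = 1, dims = c(n, n))
  list(X = X, src = el[, 1], dst = el[, 2], A = A,
       graph = rep(seq_along(graphs), ns), n_graphs = length(graphs),
       sizes = ns, n_nodes = n)
}

# neighbor sum: out_v = sum_{u in N(v)} h_u, via one gather + grouped sum
neighbor_sum <- function(h, src, dst, n) {
  out <- matrix(0, n, ncol(h))
  if (length(src) == 0L) return(out)
  rs <- rowsum(h[src, , drop = FALSE], dst)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' GIN aggregation step
#'
#' Computes `(1 + epsilon) * h_v + sum of h_u over neighbors u` for every
#' node, the pre-MLP aggregation of a GIN layer.
#'
#' @param features Numeric matrix, one row per node.
#' @param edges Two-column integer matrix of undirected edges.
#' @param epsilon Self-weight parameter.
#' @return Matrix of aggregated features, same shape as `features`.
#' @export
gin_aggregate <- function(features, edges, epsilon = 0) {
  features <- as.matrix(features)
  n <- nrow(features)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && (any(edges < 1L) || any(edges > n))) {
    stop("edge index out of range", call. = FALSE)
  }
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  (1 + epsilon) * features + neighbor_sum(features, src, dst, n)
}

#' Apply one GIN layer
#'
#' Aggregates each node with its neighbors ([gin_aggregate()]) and transforms
#' the result with the layer MLP (linear, batch norm, ReLU, linear). With
#' `mlp = NULL` the MLP is the identity, which exposes the bare aggregation
#' for testing and inspection.
#'
#' @inheritParams gin_aggregate
#' @param mlp Layer parameter list (`cmms:::gin_layer_init(d_in, d_out)`), or
#'   `NULL` for the identity map.
#' @param state Batch-norm state (running statistics); defaults to a fresh
#'   state.
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return Matrix of transformed node states.
#' @export
gin_layer <- function(features, edges, epsilon = 0, mlp = NULL, state = NULL,
                      training = FALSE) {
  agg <- gin_aggregate(features, edges, epsilon)
  if (is.null(mlp)) return(agg)
  if (is.null(state)) state <- bn_state_init(ncol(mlp$lin1$W))
  bn <- bn_fwd(agg %*% mlp$lin1$W, mlp$bn, state, training)
  r <- pmax(bn$out, 0)
  linear_fwd(r, mlp$lin2)$out
}

# full forward over a batch graph; returns pooled reps and caches
gin_fwd <- function(bg, params, state, training) {
  h <- bg$X
  K <- length(params$layers)
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    p <- params$layers[[k]]
    agg <- (1 + p$eps) * h + as.matrix(bg$A %*% h)
    a1 <- agg %*% p$lin1$W
    bn <- bn_fwd(a1, p$bn, state$layers[[k]], training)
    state$layers[[k]] <- bn$state
    r <- pmax(bn$out, 0)
    l2 <- linear_fwd(r, p$lin2)
    caches[[k]] <- list(h_in = h, agg = agg, bn_cache = bn$cache,
                        bn_out = bn$out, r = r)
    h <- l2$out
  }
  pool <- pool_fwd(h, bg)
  list(p = pool$p, node_reps = h, caches = caches, pool_cache = pool$cache,
       state = state)
}

pool_fwd <- function(h, bg) {
  ng <- bg$n_graphs
  d <- ncol(h)
  mx <- matrix(0, ng, d)
  argmx <- matrix(0L, ng, d)
  rows <- split(seq_len(bg$n_nodes), bg$graph)
  for (g in seq_len(ng)) {
    idx <- rows[[g]]
    sub <- h[idx, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    argmx[g, ] <- idx[am]
    mx[g, ] <- sub[cbind(am, seq_len(d))]
  }
  mn <- rowsum(h, bg$graph) / bg$sizes
  list(p = cbind(mx, mn), cache = list(argmx = argmx, d = d))
}

pool_bwd <- function(dp, bg, cache) {
  d <- cache$d
  dmax <- dp[, seq_len(d), drop = FALSE]
  dmean <- dp[, d + seq_len(d), drop = FALSE]
  dh <- (dmean / bg$sizes)[bg$graph, , drop = FALSE]
  for (g in seq_len(bg$n_graphs)) {
    idx <- cbind(cache$argmx[g, ], seq_len(d))
    dh[idx] <- dh[idx] + dmax[g, ]
  }
  dh
}

gin_bwd <- function(bg, params, fwd, dp) {
  dh <- pool_bwd(dp, bg, fwd$pool_cache)
  K <- length(params$layers)
  grads <- list(layers = vector("list", K))
  for (k in rev(seq_len(K))) {
    p <- params$layers[[k]]
    cc <- fwd$caches[[k]]
    l2b <- linear_bwd(list(x = cc$r), dh, p$lin2)
    dr <- l2b$dx * (cc$bn_out > 0)
    bnb <- bn_bwd(cc$bn_cache, dr, p$bn)
    da1 <- bnb$dx
    dagg <- da1 %*% t(p$lin1$W)
    deps <- sum(dagg * cc$h_in)
    dh <- (1 + p$eps) * dagg + as.matrix(bg$A %*% dagg)
    grads$layers[[k]] <- list(lin1 = list(W = crossprod(cc$agg, da1)),
                              bn = bnb$grads,
                              lin2 = l2b$grads, eps = deps)
  }
  list(grads = grads, dX = dh)
}

#' Encode a molecular graph into its pooled structure representation
#'
#' Applies `K` GIN layers and concatenates global max-pooling and global
#' mean-pooling of the final node states, yielding a vector of length
#' `2 * d_g` (512 under the package defaults).
#'
#' @param graph A `mol_graph`.
#' @param params GIN parameter list (`cmms:::gin_init(d_in, d_g, K)` or from
#'   a fitted model).
#' @param state Batch-norm running state; defaults to a fresh state (useful
#'   for architecture tests; fitted models carry their own).
#' @param training Use batch statistics instead of running statistics.
#' @return Numeric vector of length `2 * d_g`.
#' @export
encode_graph <- function(graph, params, state = NULL, training = FALSE) {
  stopifnot(inherits(graph, "mol_graph"))
  if (is.null(state)) {
    state <- gin_state_init(ncol(params$layers[[1]]$lin1$W),
                            length(params$layers))
  }
  bg <- batch_graphs(list(graph))
  out <- gin_fwd(bg, params, state, training)
  out$p[1, ]
}
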