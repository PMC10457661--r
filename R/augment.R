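# Graph augmentations for inter-view contrastive learning. The default view
# is a substructure sampled by a random walk (a connected local subgraph);
# node dropping, edge perturbation and attribute masking are provided as the
# standard comparison variants. All draw from R's RNG, so runs are
# reproducible under a fixed seed.

#' Sample a connected substructure of a molecular graph
#'
#' Performs a random walk from a uniformly chosen start atom, collecting
#' distinct nodes until `ceiling(ratio * N)` are visited (restarting from an
#' already-visited node at dead ends), and returns the node-induced subgraph
#' with features copied unchanged. If the start atom's connected component is
#' smaller than the target, the whole component is returned.
#'
#' @param graph A `mol_graph`.
#' @param ratio Target fraction of nodes to keep, in (0, 1].
#' @return A `mol_graph` with at most `ceiling(ratio * N)` nodes (always at
#'   least 1).
#' @export
sample_substructure <- function(graph, ratio = 0.4) {
  stopifnot(inherits(graph, "mol_graph"), ratio > 0, ratio <= 1)
  n <- graph$n_nodes
  target <- max(1L, as.integer(ceiling(ratio * n)))
  if (n == 1L) return(graph)
  adj <- graph$adj
  if (is.null(adj)) adj <- adjacency_list(graph)
  start <- sample.int(n, 1L)
  seen <- logical(n)
  seen[start] <- TRUE
  n_vis <- 1L
  current <- start
  # bounded walk; completion within the start component is guaranteed below
  for (step in seq_len(20L * n)) {
    if (n_vis >= target) break
    nbrs <- adj[[current]]
    if (length(nbrs) == 0L) break
    nxt <- if (length(nbrs) == 1L) nbrs else nbrs[sample.int(length(nbrs), 1L)]
    if (!seen[nxt]) {
      seen[nxt] <- TRUE
      n_vis <- n_vis + 1L
    }
    current <- nxt
  }
  # random frontier expansion finishes the sample if the walk stalled
  while (n_vis < target) {
    fresh <- setdiff(unique(unlist(adj[seen])), which(seen))
    if (length(fresh) == 0L) break
    pick <- if (length(fresh) == 1L) fresh
            else fresh[sample.int(length(fresh), 1L)]
    seen[pick] <- TRUE
    n_vis <- n_vis + 1L
  }
  induced_subgraph_mol(graph, which(seen))
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n_nodes)
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  adj
}

induced_subgraph_mol <- function(graph, keep) {
  remap <- integer(graph$n_nodes)
  remap[keep] <- seq_along(keep)
  e <- graph$edges
  sel <- e[, 1] %in% keep & e[, 2] %in% keep
  new_e <- cbind(remap[e[sel, 1]], remap[e[sel, 2]])
  structure(list(n_nodes = length(keep),
                 features = graph$features[keep, , drop = FALSE],
                 edges = matrix(as.integer(new_e), ncol = 2),
                 bond_orders = graph$bond_orders[sel],
                 atoms = if (!is.null(graph$atoms)) graph$atoms[keep, ],
                 smiles = graph$smiles),
            class = "mol_graph")
}

#' Augment a molecular graph
#'
#' Dispatches to one of the four augmentation schemes: `substructure`
#' (random-walk subgraph, see [sample_substructure()]), `node_dropping`
#' (remove `ceiling(ratio * N)` random nodes, keeping at least one, with
#' incident edges), `edge_perturbation` (remove `ceiling(ratio * |E|)` random
#' edges and add the same number of random non-edges), or `attribute_masking`
#' (replace the feature rows of `ceiling(ratio * N)` random nodes with
#' `mask_vector`).
#'
#' @param graph A `mol_graph`.
#' @param method One of `"substructure"`, `"node_dropping"`,
#'   `"edge_perturbation"`, `"attribute_masking"`.
#' @param ratio Augmentation strength; conventional defaults are 0.4 for
#'   substructure sampling, 0.2 for node dropping, 0.4 for edge perturbation
#'   and attribute masking.
#' @param mask_vector Replacement feature row for attribute masking
#'   (typically the dataset mean); defaults to this graph's column means.
#' @return An augmented `mol_graph`.
#' @export
augment_graph <- function(graph, method = c("substructure", "node_dropping",
                                            "edge_perturbation",
                                            "attribute_masking"),
                          ratio = 0.4, mask_vector = NULL) {
  method <- match.arg(method)
  n <- graph$n_nodes
  switch(method,
    substructure = sample_substructure(graph, ratio),
    node_dropping = {
      n_drop <- min(as.integer(ceiling(ratio * n)), n - 1L)
      if (n_drop <= 0L) return(graph)
      drop <- sample.int(n, n_drop)
      induced_subgraph_mol(graph, sort(setdiff(seq_len(n), drop)))
    },
    edge_perturbation = {
      e <- graph$edges
      n_e <- nrow(e)
      if (n_e == 0L || n < 2L) return(graph)
      n_mod <- min(as.integer(ceiling(ratio * n_e)), n_e)
      keep <- setdiff(seq_len(n_e), sample.int(n_e, n_mod))
      kept <- e[keep, , drop = FALSE]
      existing <- c((e[, 1] - 1L) * n + e[, 2])
      cand_u <- sample.int(n, 4L * n_mod + 8L, replace = TRUE)
      cand_v <- sample.int(n, 4L * n_mod + 8L, replace = TRUE)
      uu <- pmin(cand_u, cand_v); vv <- pmax(cand_u, cand_v)
      ok <- uu != vv & !(((uu - 1L) * n + vv) %in% existing)
      cand <- unique(cbind(uu[ok], vv[ok]))
      add <- cand[seq_len(min(n_mod, nrow(cand))), , drop = FALSE]
      g2 <- graph
      g2$edges <- matrix(as.integer(rbind(kept, add)), ncol = 2)
      g2$bond_orders <- rep(1, nrow(g2$edges))
      g2
    },
    attribute_masking = {
      n_mask <- min(as.integer(ceiling(ratio * n)), n)
      if (is.null(mask_vector)) mask_vector <- colMeans(graph$features)
      rows <- sample.int(n, n_mask)
      g2 <- graph
      g2$features[rows, ] <- matrix(mask_vector, n_mask,
                                    ncol(graph$features), byrow = TRUE)
      g2
    }
  )
}
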