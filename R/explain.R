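# Interpretability: (1) attention-derived atom and bond importances from the
# sequence encoder, and (2) Monte-Carlo edge Shapley values treating each
# bond as a player whose presence/absence changes the predicted stability,
# aggregated into a functional-group frequency report.

#' Attention-based atom and bond importance
#'
#' Runs the fitted sequence encoder over the molecule, averages the heads'
#' attention weights per token, assigns non-atom tokens (digits, bonds,
#' branches) zero atom mass and renormalizes over atom tokens, so the atom
#' weights are nonnegative and sum to 1. A bond's weight is the mean of its
#' two atoms' weights.
#'
#' @param model A fitted `cmms_model` (with sequence branch).
#' @param smiles A single SMILES string.
#' @return Object of class `cmms_explanation`: list with `smiles`, `score`,
#'   `atoms` (tibble `atom`, `symbol`, `weight`) and `bonds` (tibble `u`,
#'   `v`, `weight`).
#' @export
attention_explanation <- function(model, smiles) {
  stopifnot(inherits(model, "cmms_model"))
  if (!model$config$use_sequence) {
    stop("model was fitted without the sequence branch", call. = FALSE)
  }
  tokens <- tokenize_one(smiles)
  graph <- smiles_to_graph(smiles)
  Z <- embed_sequence(tokens, model$embeddings)
  H <- bigru_encode(Z, model$params$gru)
  ap <- attention_pool(H, model$params$att)
  token_w <- colMeans(ap$attention)          # head-averaged, sums to 1

  ti <- graph$atoms$token_index
  if (any(ti > length(tokens))) {
    stop(sprintf("token-atom alignment failed for \"%s\"", smiles),
         call. = FALSE)
  }
  aw <- token_w[ti]
  if (sum(aw) <= 0) aw <- rep(1, length(aw))
  aw <- aw / sum(aw)

  e <- graph$edges
  bw <- if (nrow(e) > 0) (aw[e[, 1]] + aw[e[, 2]]) / 2 else numeric(0)
  score <- stats::predict(model, tibble::tibble(smiles = smiles))$score

  structure(list(
    smiles = smiles, score = score, graph = graph,
    atoms = tibble::tibble(atom = seq_len(graph$n_nodes),
                           symbol = graph$atoms$symbol, weight = aw),
    bonds = tibble::tibble(u = e[, 1], v = e[, 2], weight = bw)
  ), class = "cmms_explanation")
}

#' @export
print.cmms_explanation <- function(x, ...) {
  cat(sprintf("<cmms_explanation> %s (score %.3f)\n", x$smiles, x$score))
  top <- x$atoms[order(-x$atoms$weight), ][1:min(3, nrow(x$atoms)), ]
  cat("  top atoms:",
      paste(sprintf("%s%d (%.2f)", top$symbol, top$atom, top$weight),
            collapse = ", "), "\n")
  invisible(x)
}

# value function for edge coalitions: model score with only edges S present;
# the sequence representation is held fixed. `prep` carries reusable parts.
shapley_prep <- function(model, smiles) {
  graph <- smiles_to_graph(smiles)
  s_rep <- NULL
  if (model$config$use_sequence) {
    tokens <- tokenize_one(smiles)
    Z <- embed_sequence(tokens, model$embeddings)
    H <- bigru_encode(Z, model$params$gru)
    s_rep <- attention_pool(H, model$params$att)$seq_rep
  }
  list(graph = graph, s_rep = s_rep)
}

# score E+1 nested coalition graphs (empty set, then adding edges in `ord`
# one at a time) in a single block-diagonal GIN pass
coalition_scores <- function(model, prep, ord) {
  g <- prep$graph
  N <- g$n_nodes
  E <- nrow(g$edges)
  n_copies <- E + 1L
  X <- prep$Xrep
  # copy j (0-based) holds edges ord[seq_len(j)]
  u <- g$edges[, 1]; v <- g$edges[, 2]
  copies <- lapply(seq_len(E), function(p) seq.int(p, E))
  src <- unlist(lapply(seq_len(E), function(p) {
    cp <- copies[[p]]
    c(u[ord[p]] + cp * N, v[ord[p]] + cp * N)
  }))
  dst <- unlist(lapply(seq_len(E), function(p) {
    cp <- copies[[p]]
    c(v[ord[p]] + cp * N, u[ord[p]] + cp * N)
  }))
  ntot <- n_copies * N
  A <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(ntot, ntot))
  bg <- list(X = X, A = A, graph = rep(seq_len(n_copies), each = N),
             n_graphs = n_copies, sizes = rep(N, n_copies), n_nodes = ntot)
  out <- gin_fwd(bg, model$params$gin, model$state$gin, training = FALSE)
  x <- if (is.null(prep$s_rep)) out$p
       else cbind(out$p, matrix(prep$s_rep, n_copies,
                                length(prep$s_rep), byrow = TRUE))
  h1 <- pmax(linear_fwd(x, model$params$pred1)$out, 0)
  as.numeric(sigmoid(linear_fwd(h1, model$params$pred2)$out))
}

#' Monte-Carlo edge Shapley values
#'
#' Estimates each bond's Shapley value for the coalition game whose value
#' function is the model's stability score with only a subset of bonds
#' present (node features and the sequence branch held fixed). Uses
#' permutation sampling: each random edge ordering contributes one marginal
#' `f(S + e) - f(S)` to every edge, with all coalitions of an ordering scored
#' in one batched forward pass. Standard errors come from the across-
#' permutation variance of the marginals.
#'
#' @param model A fitted `cmms_model`.
#' @param smiles A single SMILES string.
#' @param n_samples Number of sampled permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return Tibble with one row per bond: `u`, `v`, `phi` (Shapley estimate),
#'   `se` (standard error), `n_samples`; attributes `f_full` and `f_empty`
#'   carry the scores of the complete and the edgeless graph.
#' @export
edge_shapley <- function(model, smiles, n_samples = 1000L, seed = 1L) {
  stopifnot(inherits(model, "cmms_model"), n_samples >= 1L)
  prep <- shapley_prep(model, smiles)
  g <- prep$graph
  E <- nrow(g$edges)
  if (E == 0L) {
    return(tibble::tibble(u = integer(0), v = integer(0), phi = numeric(0),
                          se = numeric(0), n_samples = integer(0)))
  }
  prep$Xrep <- g$features[rep(seq_len(g$n_nodes), E + 1L), , drop = FALSE]
  sums <- numeric(E)
  sqs <- numeric(E)
  f_full <- NA_real_; f_empty <- NA_real_
  withr_seed(seed, {
    for (it in seq_len(n_samples)) {
      ord <- if (E == 1L) 1L else sample.int(E)
      sc <- coalition_scores(model, prep, ord)
      marg <- diff(sc)                       # marginal of ord[p] at step p
      sums[ord] <- sums[ord] + marg
      sqs[ord] <- sqs[ord] + marg^2
      if (it == 1L) {
        f_empty <- sc[1L]
        f_full <- sc[E + 1L]
      }
    }
  })
  phi <- sums / n_samples
  se <- if (n_samples > 1L) {
    sqrt(pmax(sqs / n_samples - phi^2, 0) / (n_samples - 1L))
  } else {
    rep(NA_real_, E)
  }
  out <- tibble::tibble(u = g$edges[, 1], v = g$edges[, 2], phi = phi,
                        se = se, n_samples = as.integer(n_samples))
  attr(out, "f_full") <- f_full
  attr(out, "f_empty") <- f_empty
  out
}

# deterministic signature of the fragment made of `bond_rows` of a graph:
# sorted multiset of typed bonds
fragment_key <- function(graph, bond_rows) {
  at <- graph$atoms
  typ <- function(a) {
    paste0(at$symbol[a], ifelse(at$aromatic[a], "ar", ""))
  }
  e <- graph$edges[bond_rows, , drop = FALSE]
  o <- graph$bond_orders[bond_rows]
  parts <- vapply(seq_len(nrow(e)), function(i) {
    ends <- sort(c(typ(e[i, 1]), typ(e[i, 2])))
    sprintf("%s-%s:%g", ends[1], ends[2], o[i])
  }, character(1))
  paste(sort(parts), collapse = "|")
}

# descriptive name for a small bond-induced fragment (reporting only)
fragment_name <- function(graph, bond_rows) {
  at <- graph$atoms
  e <- graph$edges[bond_rows, , drop = FALSE]
  o <- graph$bond_orders[bond_rows]
  atoms <- sort(unique(c(e[, 1], e[, 2])))
  sym <- at$symbol[atoms]
  arom <- at$aromatic[atoms]
  n_f <- sum(sym == "F")
  has_arom_bond <- any(o == 1.5)
  if (any(o == 3) && all(sym %in% "C")) return("acetylene")
  if (n_f >= 3) {
    return(if (any(arom)) "trifluoromethylbenzene" else "trifluoromethyl")
  }
  if (n_f >= 1 && any(arom)) return("fluorobenzene")
  if (any(sym == "Cl")) {
    return(if (any(arom)) "chlorobenzene" else "alkyl chloride")
  }
  if (any(sym == "S") && sum(sym == "O") >= 2) return("sulfonyl group")
  if (any(sym == "N") && any(o == 2 & apply(e, 1, function(b) {
    any(at$symbol[b] == "O")
  }))) return("amide")
  if (any(o == 2) && any(sym == "O") && sum(sym == "O") >= 2) return("ester")
  if (any(o == 2) && any(sym == "O")) return("carbonyl group")
  if (any(sym == "O") && !any(o == 2)) {
    deg1_o <- any(sym == "O" & at$degree[atoms] == 1)
    if (deg1_o) return("hydroxyl")
    return(if (any(arom)) "aryl ether" else "ether")
  }
  if (any(sym == "N" & arom)) return("azaheterocycle")
  if (any(sym == "N")) {
    n_idx <- atoms[sym == "N"][1]
    return(switch(min(at$degree[n_idx], 3), "primary amine",
                  "secondary amine", "tertiary amine"))
  }
  if (has_arom_bond) {
    return(if (all(arom)) "phenyl ring" else "alkylbenzene")
  }
  if (all(sym == "C")) return("alkyl chain")
  "ring"
}

#' Frequency report of high-impact substructures
#'
#' For every explained molecule, selects the bonds whose Shapley value
#' exceeds `threshold`; each such bond together with its neighboring bonds
#' (bonds sharing an atom) defines a substructure instance. Instances are
#' keyed by a canonical fragment signature, counted separately for molecules
#' predicted stable and unstable, and the most frequent `top` substructures
#' per class are returned with their share of instances.
#'
#' @param explanations List; each element must carry `shapley` (an
#'   [edge_shapley()] tibble), `graph` (the `mol_graph`) and `predicted`
#'   (predicted class, 1 = stable), as produced by [explain_molecules()].
#' @param threshold Shapley cutoff for a "critical" bond (default 0.2).
#' @param top Rows per class (default 10).
#' @return Tibble with `class` (`stable`/`unstable`), `rank`, `group`
#'   (descriptive name), `key` (fragment signature), `count`, `percent`.
#' @export
group_frequency_report <- function(explanations, threshold = 0.2, top = 10L) {
  rows <- list()
  for (ex in explanations) {
    sh <- ex$shapley
    g <- ex$graph
    if (is.null(sh) || nrow(sh) == 0L) next
    crit <- which(sh$phi > threshold)
    for (b in crit) {
      ends <- c(sh$u[b], sh$v[b])
      nb <- which(g$edges[, 1] %in% ends | g$edges[, 2] %in% ends)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = if (ex$predicted == 1L) "stable" else "unstable",
        key = fragment_key(g, nb),
        group = fragment_name(g, nb))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(class = character(0), rank = integer(0),
                          group = character(0), key = character(0),
                          count = integer(0), percent = numeric(0)))
  }
  inst <- dplyr::bind_rows(rows)
  out <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(
      dplyr::count(inst, .data$class, .data$key, .data$group,
                   name = "count"),
      .data$class),
    percent = 100 * .data$count / sum(.data$count)))
  out <- dplyr::slice_head(
    dplyr::group_by(dplyr::arrange(out, .data$class,
                                   dplyr::desc(.data$count)), .data$class),
    n = top)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  dplyr::ungroup(out)[, c("class", "rank", "group", "key", "count",
                          "percent")]
}

#' Explain a set of molecules with both procedures
#'
#' Convenience wrapper: per molecule, computes the attention explanation and
#' (optionally) edge Shapley values, plus the model's predicted class.
#'
#' @param model A fitted `cmms_model`.
#' @param smiles Character vector.
#' @param n_samples Shapley permutations per molecule; `0` skips Shapley.
#' @param seed Base seed (molecule i uses `seed + i`).
#' @return List of explanation records (`smiles`, `predicted`, `score`,
#'   `attention` (a `cmms_explanation`), `shapley`, `graph`).
#' @export
explain_molecules <- function(model, smiles, n_samples = 1000L, seed = 1L) {
  pred <- stats::predict(model, tibble::tibble(smiles = smiles))
  lapply(seq_along(smiles), function(i) {
    att <- if (model$config$use_sequence) {
      attention_explanation(model, smiles[i])
    }
    sh <- if (n_samples > 0L) {
      edge_shapley(model, smiles[i], n_samples = n_samples, seed = seed + i)
    }
    g <- if (!is.null(att)) att$graph else smiles_to_graph(smiles[i])
    list(smiles = smiles[i], predicted = pred$class[i], score = pred$score[i],
         attention = att, shapley = sh, graph = g)
  })
}
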