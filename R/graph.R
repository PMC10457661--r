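# Molecular graph construction and the 84-dimensional binary atom featurization.
#
# The graph is a heavy-atom graph: hydrogens are implicit and enter only
# through the per-atom hydrogen-count feature. Atom indices are 1-based; each
# undirected bond is stored once as a (u, v) pair with u < v and expanded to
# both directions inside the encoders.

# symbol vocabulary for the one-hot block: 49 elements + trailing "unknown"
.symbol_list <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "I",
  "B", "H", "Se", "Na", "K", "Li", "Ca", "Mg", "Zn", "Fe",
  "Cu", "Mn", "Co", "Ni", "As", "Al", "Sn", "Ag", "Pd", "Pt",
  "Au", "Hg", "Cd", "Cr", "Ti", "V", "Mo", "W", "Pb", "Bi",
  "Sb", "Ba", "Sr", "Tl", "In", "Ge", "Ga", "Zr", "Te", "unknown"
)

.default_valence <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph of a molecule together with the binary atom
#' feature matrix used by the graph encoder. Each atom row encodes five
#' property families as 84 binary indicators: element symbol (one-hot over a
#' fixed 50-slot vocabulary whose last slot collects unknown elements), heavy
#' degree (one-hot 0-10), number of attached hydrogens (one-hot 0-10),
#' implicit valence (one-hot 0-10) and an aromaticity flag.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier carried into error messages.
#' @return An object of class `mol_graph`: a list with `n_nodes`, `features`
#'   (an `n_nodes` x 84 binary matrix), `edges` (two-column integer matrix,
#'   one row per undirected bond, first column < second), and `atoms`, a
#'   tibble with per-atom `symbol`, `aromatic`, `degree`, `n_hydrogens`,
#'   `implicit_valence`, `charge` and `token_index` (position of the atom's
#'   token in [tokenize_smiles()] output).
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$n_nodes
#' nrow(g$edges)
#' @export
smiles_to_graph <- function(smiles, id = NULL) {
  tokens <- tryCatch(tokenize_one(smiles), error = function(e) {
    stop(smiles_err(conditionMessage(e), id), call. = FALSE)
  })
  parse_tokens_to_graph(tokens, smiles, id)
}

smiles_err <- function(msg, id) {
  if (is.null(id)) msg else sprintf("[id %s] %s", id, msg)
}

parse_bracket_atom <- function(tok) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  # strip isotope
  body <- sub("^[0-9]+", "", body)
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", body))
  if (length(m) == 0L) stop(sprintf("cannot parse bracket atom '%s'", tok),
                            call. = FALSE)
  sym_raw <- m
  rest <- substr(body, nchar(sym_raw) + 1L, nchar(body))
  aromatic <- sym_raw %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  symbol <- if (aromatic) {
    paste0(toupper(substr(sym_raw, 1, 1)), substr(sym_raw, 2, nchar(sym_raw)))
  } else sym_raw
  rest <- gsub("@", "", rest, fixed = TRUE)
  hcount <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L && nzchar(hm)) {
    hcount <- if (hm == "H") 1L else as.integer(substr(hm, 2L, nchar(hm)))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*([+-]*)", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    if (grepl("^[+-][0-9]+$", cm)) {
      charge <- as.integer(cm)
    } else {
      sgn <- if (substr(cm, 1, 1) == "+") 1L else -1L
      charge <- sgn * nchar(gsub("[^+-]", "", cm))
    }
  }
  list(symbol = symbol, aromatic = aromatic, hcount = hcount,
       charge = charge, explicit_h = TRUE)
}

parse_tokens_to_graph <- function(tokens, smiles, id = NULL) {
  sym <- character(0); arom <- logical(0); hexp <- integer(0)
  has_h <- logical(0); chg <- integer(0); tok_idx <- integer(0)
  edges_u <- integer(0); edges_v <- integer(0); orders <- numeric(0)

  prev_stack <- integer(0)   # branch stack
  prev <- 0L                 # current attachment atom (0 = none)
  pending_bond <- NA_real_   # order of bond symbol seen since last atom
  ring_open <- list()        # digit -> list(atom, order)
  n_atom <- 0L

  add_atom <- function(symbol, aromatic, hcount, charge, explicit_h, ti) {
    n_atom <<- n_atom + 1L
    sym[n_atom] <<- symbol; arom[n_atom] <<- aromatic
    hexp[n_atom] <<- hcount; has_h[n_atom] <<- explicit_h
    chg[n_atom] <<- charge; tok_idx[n_atom] <<- ti
    if (prev > 0L) {
      ord <- if (is.na(pending_bond)) {
        if (arom[prev] && aromatic) 1.5 else 1
      } else pending_bond
      edges_u <<- c(edges_u, prev); edges_v <<- c(edges_v, n_atom)
      orders <<- c(orders, ord)
    }
    prev <<- n_atom
    pending_bond <<- NA_real_
  }

  for (ti in seq_along(tokens)) {
    tok <- tokens[[ti]]
    if (startsWith(tok, "[")) {
      a <- parse_bracket_atom(tok)
      add_atom(a$symbol, a$aromatic, a$hcount, a$charge, TRUE, ti)
    } else if (tok %in% c(.single_atoms, "Cl", "Br")) {
      aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
      symbol <- if (aromatic) toupper(tok) else tok
      add_atom(symbol, aromatic, 0L, 0L, FALSE, ti)
    } else if (tok %in% .bond_chars) {
      pending_bond <- switch(tok, "-" = 1, "/" = 1, "\\" = 1,
                             "=" = 2, "#" = 3, ":" = 1.5, 1)
    } else if (tok == "(") {
      prev_stack <- c(prev_stack, prev)
    } else if (tok == ")") {
      if (length(prev_stack) == 0L) {
        stop(smiles_err(sprintf("unbalanced ')' at token %d in \"%s\"",
                                ti, smiles), id), call. = FALSE)
      }
      prev <- prev_stack[[length(prev_stack)]]
      prev_stack <- prev_stack[-length(prev_stack)]
    } else if (grepl("^%?[0-9]+$", tok)) {
      key <- sub("^%", "", tok)
      if (prev == 0L) {
        stop(smiles_err(sprintf("ring closure before any atom in \"%s\"",
                                smiles), id), call. = FALSE)
      }
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, order = pending_bond)
      } else {
        other <- ring_open[[key]]
        ord <- if (!is.na(pending_bond)) pending_bond
               else if (!is.na(other$order)) other$order
               else if (arom[prev] && arom[other$atom]) 1.5 else 1
        u <- min(prev, other$atom); v <- max(prev, other$atom)
        if (u == v) stop(smiles_err("ring closure forms a self-loop", id),
                         call. = FALSE)
        edges_u <- c(edges_u, u); edges_v <- c(edges_v, v)
        orders <- c(orders, ord)
        ring_open[[key]] <- NULL
      }
      pending_bond <- NA_real_
    } else if (tok == ".") {
      prev <- 0L
      pending_bond <- NA_real_
    } else {
      stop(smiles_err(sprintf("unexpected token '%s' in \"%s\"", tok, smiles),
                      id), call. = FALSE)
    }
  }
  if (length(prev_stack) > 0L) {
    stop(smiles_err(sprintf("unbalanced '(' in \"%s\"", smiles), id),
         call. = FALSE)
  }
  if (length(ring_open) > 0L) {
    stop(smiles_err(sprintf("unclosed ring bond(s) %s in \"%s\"",
                            paste(names(ring_open), collapse = ","), smiles),
         id), call. = FALSE)
  }
  if (n_atom == 0L) {
    stop(smiles_err(sprintf("no atoms in \"%s\"", smiles), id), call. = FALSE)
  }

  edges <- unique(cbind(pmin(edges_u, edges_v), pmax(edges_u, edges_v)))
  storage.mode(edges) <- "integer"
  ord_map <- orders[!duplicated(cbind(pmin(edges_u, edges_v),
                                      pmax(edges_u, edges_v)))]

  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_atom)
  bond_sum <- rep(0, n_atom)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      o <- if (ord_map[e] == 1.5) 1 else ord_map[e]
      bond_sum[edges[e, 1]] <- bond_sum[edges[e, 1]] + o
      bond_sum[edges[e, 2]] <- bond_sum[edges[e, 2]] + o
    }
  }
  # implicit hydrogens by the smallest standard valence covering the bond sum;
  # aromatic atoms carry one delocalised bond beyond their explicit ring bonds
  n_h <- integer(n_atom); impl_val <- integer(n_atom)
  for (a in seq_len(n_atom)) {
    if (has_h[a]) {
      n_h[a] <- hexp[a]
      impl_val[a] <- 0L
    } else {
      vals <- .default_valence[[sym[a]]]
      eff <- bond_sum[a] + as.integer(arom[a])
      if (is.null(vals)) {
        n_h[a] <- 0L
      } else {
        v <- vals[vals >= eff]
        n_h[a] <- if (length(v) == 0L) 0L else as.integer(v[1] - eff)
      }
      impl_val[a] <- n_h[a]
    }
  }

  atoms <- tibble::tibble(
    symbol = sym, aromatic = arom, degree = as.integer(degree),
    n_hydrogens = n_h, implicit_valence = impl_val, charge = chg,
    token_index = tok_idx
  )
  structure(
    list(
      n_nodes = n_atom,
      features = atom_feature_matrix(atoms),
      edges = edges,
      bond_orders = ord_map,
      atoms = atoms,
      smiles = smiles
    ),
    class = "mol_graph"
  )
}

one_hot <- function(value, n_slots, clamp_last = TRUE) {
  v <- rep(0, n_slots)
  idx <- value + 1L
  if (idx > n_slots) idx <- if (clamp_last) n_slots else stop("out of range")
  v[idx] <- 1
  v
}

#' Build the 84-dimensional binary feature matrix for a set of atoms
#'
#' Layout: element one-hot (50, last slot = unknown), heavy degree one-hot
#' (0-10), attached-hydrogen count one-hot (0-10), implicit valence one-hot
#' (0-10), aromatic flag (1). Counts above 10 land in the last slot of their
#' block.
#'
#' @param atoms Tibble as found in `mol_graph$atoms`.
#' @return Numeric matrix with one row per atom and 84 columns.
#' @keywords internal
atom_feature_matrix <- function(atoms) {
  n <- nrow(atoms)
  feats <- matrix(0, n, 84L)
  for (a in seq_len(n)) {
    si <- match(atoms$symbol[a], .symbol_list)
    if (is.na(si)) si <- length(.symbol_list)
    row <- c(one_hot(si - 1L, 50L),
             one_hot(min(atoms$degree[a], 10L), 11L),
             one_hot(min(atoms$n_hydrogens[a], 10L), 11L),
             one_hot(min(atoms$implicit_valence[a], 10L), 11L),
             as.numeric(atoms$aromatic[a]))
    feats[a, ] <- row
  }
  feats
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d aromatic atoms\n",
              x$smiles, x$n_nodes, nrow(x$edges), sum(x$atoms$aromatic)))
  invisible(x)
}

#' Construct a mol_graph directly from nodes and edges
#'
#' Low-level constructor used by the augmentation routines, the synthetic
#' fixtures and tests. No chemistry is implied: features may be any numeric
#' matrix.
#'
#' @param features Numeric matrix, one row per node.
#' @param edges Two-column integer matrix of undirected edges (may have zero
#'   rows); self-loops and out-of-range endpoints are rejected.
#' @param smiles Optional label.
#' @return A `mol_graph`.
#' @export
make_graph <- function(features, edges = matrix(integer(0), 0, 2),
                       smiles = NA_character_) {
  features <- as.matrix(features)
  edges <- matrix(as.integer(edges), ncol = 2)
  n <- nrow(features)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
  }
  structure(list(n_nodes = n, features = features, edges = edges,
                 bond_orders = rep(1, nrow(edges)), atoms = NULL,
                 smiles = smiles),
            class = "mol_graph")
}
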