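# Smi2Vec-style token embeddings: skip-gram with negative sampling trained on
# tokenized SMILES, so that tokens appearing in similar local chemical
# contexts receive nearby vectors. Implemented as vectorised minibatch SGD
# (no word2vec backend is assumed); fully deterministic under a fixed seed.

#' Train per-token atom embeddings on a tokenized SMILES corpus
#'
#' Skip-gram with negative sampling over a symmetric context window. Both
#' input and context vector tables are learned; the input table is returned.
#' Tokens absent from the corpus at lookup time receive a deterministic
#' seeded fallback vector (see [embed_sequence()]).
#'
#' @param corpus List of character vectors, one tokenized SMILES per element
#'   (see [tokenize_smiles()]).
#' @param d1 Embedding dimension (default 100).
#' @param window Symmetric context window size (default 5).
#' @param epochs Training epochs (default 10).
#' @param seed Integer seed controlling initialization, shuffling and
#'   negative sampling.
#' @param negative Number of negative samples per pair (default 5).
#' @param lr Initial learning rate, decayed linearly across epochs.
#' @param oov_seed Seed for the out-of-vocabulary fallback (defaults to
#'   `seed`).
#' @return An object of class `embedding_table`: list with `vocab` (named
#'   integer index), `vectors` (|vocab| x d1 matrix), `d1`, `oov_seed`.
#' @export
train_atom_embeddings <- function(corpus, d1 = 100L, window = 5L,
                                  epochs = 10L, seed = 1L, negative = 5L,
                                  lr = 0.025, oov_seed = seed) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (any(lengths(corpus) < 1L)) stop("empty sentence in corpus", call. = FALSE)
  stopifnot(d1 >= 1L, window >= 1L, epochs >= 1L)

  types <- sort(unique(unlist(corpus)))
  vocab <- stats::setNames(seq_along(types), types)
  V <- length(types)

  # (center, context) pairs over the whole corpus
  cen_l <- vector("list", length(corpus))
  ctx_l <- vector("list", length(corpus))
  for (si in seq_along(corpus)) {
    idx <- unname(vocab[corpus[[si]]])
    m <- length(idx)
    if (m < 2L) next
    cc <- vector("list", min(window, m - 1L))
    for (off in seq_len(min(window, m - 1L))) {
      a <- idx[seq_len(m - off)]; b <- idx[(off + 1L):m]
      cc[[off]] <- rbind(c(a, b), c(b, a))
    }
    pairs <- do.call(cbind, cc)
    cen_l[[si]] <- pairs[1L, ]; ctx_l[[si]] <- pairs[2L, ]
  }
  centers <- unlist(cen_l); contexts <- unlist(ctx_l)
  counts <- tabulate(unname(vocab[unlist(corpus)]), nbins = V)
  neg_prob <- counts^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  withr_seed(seed, {
    W <- matrix(stats::runif(V * d1, -0.5, 0.5) / d1, V, d1)
    C <- matrix(0, V, d1)
    n_pairs <- length(centers)
    if (n_pairs > 0L) {
      # Within a minibatch every pair with the same (center type, context
      # type) contributes the identical gradient, so the SGD step collapses
      # to a V x V pair-count tabulation followed by two small matrix
      # products -- an exact reformulation of per-pair updates.
      batch <- 32L
      for (ep in seq_len(epochs)) {
        rate <- lr * max(1 - (ep - 1) / epochs, 1e-3)
        perm <- sample.int(n_pairs)
        for (start in seq(1L, n_pairs, by = batch)) {
          sel <- perm[start:min(start + batch - 1L, n_pairs)]
          ci <- centers[sel]; oi <- contexts[sel]
          B <- length(sel)
          ni <- sample.int(V, B * negative, replace = TRUE, prob = neg_prob)

          D <- tcrossprod(W, C)                       # all type-pair dots
          Np <- matrix(tabulate((ci - 1L) * V + oi, V * V), V, V,
                       byrow = TRUE)
          Nn <- matrix(tabulate((rep(ci, times = negative) - 1L) * V + ni,
                                V * V), V, V, byrow = TRUE)
          M <- Np * (plogis(D) - 1) + Nn * plogis(D)  # summed dL/d(dot)
          dW <- M %*% C
          dC <- crossprod(M, W)
          W <- W - rate * dW
          C <- C - rate * dC
        }
      }
    }
    structure(list(vocab = vocab, vectors = W, d1 = as.integer(d1),
                   oov_seed = as.integer(oov_seed)),
              class = "embedding_table")
  })
}

# deterministic fallback vector for a token outside the vocabulary
oov_vector <- function(token, d1, oov_seed) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 131 + code) %% 2147480009
  h <- (h + as.numeric(oov_seed) * 7919) %% 2147480009
  withr_seed(as.integer(h), stats::runif(d1, -0.05, 0.05))
}

#' Look up the embedding matrix of a token sequence
#'
#' Row t of the result is the embedding of token t. Tokens not in the table's
#' vocabulary receive a deterministic random vector that depends only on the
#' token string and the table's `oov_seed`, so repeated lookups agree.
#'
#' @param tokens Character vector of tokens.
#' @param table An `embedding_table` from [train_atom_embeddings()].
#' @return Numeric matrix `length(tokens)` x `d1`.
#' @export
embed_sequence <- function(tokens, table) {
  stopifnot(inherits(table, "embedding_table"), length(tokens) >= 1L)
  idx <- table$vocab[tokens]
  Z <- matrix(0, length(tokens), table$d1)
  known <- !is.na(idx)
  if (any(known)) Z[known, ] <- table$vectors[idx[known], , drop = FALSE]
  for (t in which(!known)) {
    Z[t, ] <- oov_vector(tokens[t], table$d1, table$oov_seed)
  }
  Z
}

#' Write an embedding table in word2vec text format
#'
#' First line `"<vocab size> <dimension>"`, then one token per line followed
#' by its vector.
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(table$vocab), table$d1), con)
  toks <- names(table$vocab)
  for (i in order(unname(table$vocab))) {
    writeLines(paste(toks[i], paste(formatC(table$vectors[table$vocab[[i]], ],
                                            format = "g", digits = 17),
                                    collapse = " ")), con)
  }
  invisible(path)
}

#' Read an embedding table from word2vec text format
#'
#' @param path Path to a word2vec-format text file.
#' @param oov_seed Seed for out-of-vocabulary fallbacks.
#' @return An `embedding_table`.
#' @export
read_embeddings <- function(path, oov_seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  V <- hdr[1]; d1 <- hdr[2]
  toks <- character(V)
  W <- matrix(0, V, d1)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    toks[i] <- parts[1]
    W[i, ] <- as.numeric(parts[-1])
  }
  structure(list(vocab = stats::setNames(seq_len(V), toks), vectors = W,
                 d1 = d1, oov_seed = as.integer(oov_seed)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens, dimension %d\n",
              length(x$vocab), x$d1))
  invisible(x)
}
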