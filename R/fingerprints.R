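# Circular fingerprints and Tanimoto similarity (via OpenBabel's ECFP
# implementation exposed through ChemmineR), used for dataset similarity
# audits and the structural-cluster split.

#' Extended-connectivity fingerprints for a set of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param type Fingerprint type passed to the chemistry toolkit (default
#'   `"ECFP4"`, i.e. circular with radius 2).
#' @return Logical matrix with one row per molecule and one column per bit.
#' @export
ecfp_fingerprints <- function(smiles, type = "ECFP4") {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, type))
  m <- methods::slot(fp, "fpma") > 0
  rownames(m) <- smiles
  m
}

tanimoto_bits <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Tanimoto similarity between two molecules on ECFP bits
#'
#' Computes |A intersect B| / |A union B| over the on-bits of the two
#' molecules' circular fingerprints. Two molecules with no on-bits in common
#' score 0; identical molecules score 1.
#'
#' @param smiles_a,smiles_b SMILES strings (each length 1).
#' @inheritParams ecfp_fingerprints
#' @return Similarity in \[0, 1\].
#' @export
ecfp_tanimoto <- function(smiles_a, smiles_b, type = "ECFP4") {
  m <- ecfp_fingerprints(c(smiles_a, smiles_b), type = type)
  tanimoto_bits(m[1, ], m[2, ])
}

#' Pairwise Tanimoto similarity matrix
#'
#' @inheritParams ecfp_fingerprints
#' @return Symmetric numeric matrix of pairwise Tanimoto similarities with
#'   unit diagonal.
#' @export
tanimoto_matrix <- function(smiles, type = "ECFP4") {
  m <- ecfp_fingerprints(smiles, type = type)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  on <- rowSums(m)
  un <- outer(on, on, "+") - inter
  s <- ifelse(un == 0, 0, inter / pmax(un, .Machine$double.eps))
  diag(s) <- 1
  dimnames(s) <- NULL
  s
}

#' Bin a Tanimoto similarity score into the conventional categories
#'
#' Scores up to 0.5 are `dissimilar`, above 0.5 and up to 0.7
#' `moderately_similar`, and above 0.7 `highly_similar`.
#'
#' @param score Numeric vector of similarities in \[0, 1\].
#' @return Factor with levels `dissimilar`, `moderately_similar`,
#'   `highly_similar`.
#' @examples
#' similarity_bin(c(0.47, 0.5, 0.71))
#' @export
similarity_bin <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 0.5, 0.7, Inf),
      labels = c("dissimilar", "moderately_similar", "highly_similar"))
}

#' Canonicalize SMILES strings
#'
#' Uses the chemistry toolkit's canonical SMILES writer; used for duplicate
#' removal where different SMILES spellings denote the same molecule.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES; unparseable inputs yield
#'   `NA`.
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- vapply(smiles, function(s) {
    !inherits(tryCatch(tokenize_one(s), error = identity), "error")
  }, logical(1))
  if (!any(ok)) return(out)
  res <- tryCatch({
    txt <- ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(paste(smiles[ok], collapse = "\n"), "\n"))
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    sub("\t.*$", "", trimws(lines))
  }, error = function(e) rep(NA_character_, sum(ok)))
  if (length(res) == sum(ok)) {
    res[!nzchar(res)] <- NA_character_
    out[ok] <- res
  }
  out
}
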