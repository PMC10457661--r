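#' Tokenize a SMILES string into atom and symbol tokens
#'
#' Splits a SMILES string left-to-right into the token alphabet used by the
#' sequence encoder: one token per atom (two-letter organic-subset halogens
#' `Cl`/`Br` and complete bracket atoms such as `[nH]` or `[O-]` are single
#' tokens), and one token per ring-closure digit, bond symbol, branch
#' parenthesis or dot. Concatenating the tokens in order reproduces the input
#' exactly.
#'
#' @param smiles Character vector of SMILES strings.
#' @return For a single input string, a character vector of tokens; for a
#'   vector input, a list of such vectors (named by the input).
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("c1ccccc1Cl")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- lapply(smiles, tokenize_one)
  if (length(smiles) == 1L) out[[1L]] else stats::setNames(out, smiles)
}

# single-char tokens permitted outside brackets
.single_atoms <- c("B", "C", "N", "O", "P", "S", "F", "I",
                   "b", "c", "n", "o", "p", "s")
.bond_chars <- c("-", "=", "#", ":", "/", "\\", "~", "$")
.struct_chars <- c("(", ")", ".")

tokenize_one <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop("SMILES must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unbalanced '[' at offset %d in \"%s\"", i, smiles),
             call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unbalanced ']' at offset %d in \"%s\"", i, smiles),
           call. = FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        stop(sprintf("invalid '%%' ring closure at offset %d in \"%s\"",
                     i, smiles), call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[[i + 1L]] %in% c("l", "r") &&
               paste0(ch, chars[[i + 1L]]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[[i + 1L]]))
      i <- i + 2L
    } else if (ch %in% .single_atoms || grepl("[0-9]", ch) ||
               ch %in% .bond_chars || ch %in% .struct_chars) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unrecognised SMILES character '%s' at offset %d in \"%s\"",
                   ch, i, smiles), call. = FALSE)
    }
  }
  tokens
}

#' Classify SMILES tokens as atoms or structural symbols
#'
#' @param tokens Character vector of tokens from [tokenize_smiles()].
#' @return Logical vector, `TRUE` where the token denotes an atom.
#' @export
is_atom_token <- function(tokens) {
  startsWith(tokens, "[") |
    tokens %in% c(.single_atoms, "Cl", "Br")
}
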