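#' Read a labelled molecule table
#'
#' Reads a delimited text file with a `smiles` column and a binary `label`
#' column (1 = metabolically stable), drops rows whose SMILES cannot be
#' parsed, and optionally removes duplicate molecules by canonical SMILES
#' (first occurrence wins). The counts of removed rows are attached as the
#' `dedupe_report` attribute and also available via [dedupe_report()].
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, or set `delim`).
#' @param dedupe Remove canonical-SMILES duplicates (default `TRUE`).
#' @param delim Field delimiter; default `","` unless the path ends in
#'   `.tsv`/`.txt`, then `"\t"`.
#' @return A tibble with columns `id`, `smiles`, `label`, carrying a
#'   `dedupe_report` attribute (`n_input`, `n_parse_failed`, `n_duplicates`,
#'   `n_kept`) and `provenance` attribute (the source path).
#' @export
read_molecules <- function(path, dedupe = TRUE, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("smiles", "label") %in% names(df))) {
    stop("input must have 'smiles' and 'label' columns", call. = FALSE)
  }
  if (!all(df$label %in% c(0, 1))) {
    stop("labels must be 0 (unstable) or 1 (stable)", call. = FALSE)
  }
  n_input <- nrow(df)
  if (!"id" %in% names(df)) df$id <- sprintf("mol%05d", seq_len(nrow(df)))
  df$id <- as.character(df$id)

  parseable <- vapply(df$smiles, function(s) {
    !inherits(tryCatch(smiles_to_graph(s), error = identity), "error")
  }, logical(1))
  n_parse_failed <- sum(!parseable)
  df <- df[parseable, , drop = FALSE]

  n_duplicates <- 0L
  if (dedupe && nrow(df) > 0) {
    canon <- canonical_smiles(df$smiles)
    canon[is.na(canon)] <- df$smiles[is.na(canon)]
    dup <- duplicated(canon)
    n_duplicates <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid molecules in input", call. = FALSE)

  out <- tibble::tibble(id = df$id, smiles = df$smiles,
                        label = as.integer(df$label))
  attr(out, "dedupe_report") <- list(
    n_input = n_input, n_parse_failed = n_parse_failed,
    n_duplicates = n_duplicates, n_kept = nrow(out))
  attr(out, "provenance") <- path
  out
}

#' Retrieve the dedupe/parse report of a molecule table
#'
#' @param data A tibble returned by [read_molecules()].
#' @return A list with `n_input`, `n_parse_failed`, `n_duplicates`, `n_kept`.
#' @export
dedupe_report <- function(data) {
  r <- attr(data, "dedupe_report")
  if (is.null(r)) stop("data carries no dedupe report", call. = FALSE)
  r
}

#' Write a molecule table and its dedupe report
#'
#' @param data Tibble with `id`, `smiles`, `label`.
#' @param path Output CSV path; the dedupe report, if present, is written
#'   alongside as `<path>.report.json`.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(data, path) {
  utils::write.csv(data[, c("id", "smiles", "label")], path,
                   row.names = FALSE, quote = FALSE)
  r <- attr(data, "dedupe_report")
  if (!is.null(r)) {
    jsonlite::write_json(r, paste0(path, ".report.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an unlabelled SMILES corpus (.smi, one SMILES per line)
#'
#' @param path Path to the corpus file.
#' @return Character vector of SMILES (unparseable lines dropped with a
#'   message).
#' @export
read_smiles_corpus <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("[ \t].*$", "", lines)
  lines <- lines[nzchar(lines)]
  ok <- vapply(lines, function(s) {
    !inherits(tryCatch(tokenize_one(s), error = identity), "error")
  }, logical(1))
  if (any(!ok)) message(sprintf("dropped %d unparseable line(s)", sum(!ok)))
  if (!any(ok)) stop("no parseable SMILES in corpus", call. = FALSE)
  unname(lines[ok])
}
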