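# Evaluation protocols: stratified k-fold cross-validation, leave-one-
# structural-cluster-out validation on ECFP-Tanimoto K-means clusters, and a
# sweep over the contrastive loss weight.

#' Stratified k-fold cross-validation
#'
#' Splits the molecules into `folds` stratified folds (every molecule is in
#' exactly one test fold), fits the model on each training portion and
#' evaluates on the held-out fold.
#'
#' @param data Labelled molecule tibble (`smiles`, `label`).
#' @param config A [cmms_config()]; `config$seed` controls the partition and
#'   all fits (fold f of repeat r uses a seed derived from it).
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions with different partitions.
#' @param embeddings Optional shared embedding table.
#' @param verbose Print per-fold progress.
#' @return Tibble with one row per fold and repeat (`repeat_`, `fold`, `auc`,
#'   `accuracy`, `f1`, `mcc`, `n`); the mean/sd aggregate is attached as the
#'   `aggregate` attribute and printed by [crossval_summary()].
#' @export
cmms_crossval <- function(data, config = cmms_config(), folds = 10L,
                          repeats = 1L, embeddings = NULL, verbose = FALSE) {
  stopifnot(folds >= 2L, repeats >= 1L)
  y <- data$label
  if (min(table(y)) < folds) {
    stop("more folds than molecules in the rarest class", call. = FALSE)
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- withr_seed(config$seed + 1000L * r,
                          stratified_folds(y, folds))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      cfg <- config
      cfg$seed <- config$seed + 1000L * r + f
      fit <- cmms_fit(data[!te, , drop = FALSE], cfg,
                      embeddings = embeddings)
      pr <- stats::predict(fit, data[te, , drop = FALSE])
      mt <- evaluate_predictions(dplyr::mutate(pr, label = y[te]))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = f), mt)
      if (verbose) {
        message(sprintf("repeat %d fold %d: AUC %.3f ACC %.3f", r, f,
                        mt$auc, mt$accuracy))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "aggregate") <- crossval_summary(out)
  out
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' @param fold_metrics Tibble with columns `auc`, `accuracy`, `f1`, `mcc`.
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`.
#' @export
crossval_summary <- function(fold_metrics) {
  long <- tidyr::pivot_longer(
    fold_metrics[, c("auc", "accuracy", "f1", "mcc")],
    cols = dplyr::everything(), names_to = "metric")
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value), sd = stats::sd(.data$value),
                   .groups = "drop")
}

# fold assignment stratified by label, as balanced as possible
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Cluster molecules by structural similarity
#'
#' Computes the pairwise ECFP-Tanimoto similarity matrix and runs K-means on
#' its rows, so each molecule is described by its similarity profile to all
#' others. Used for leave-one-cluster-out validation of generalization to
#' novel chemotypes.
#'
#' @param smiles Character vector of SMILES.
#' @param k Number of clusters (default 5).
#' @param seed Seed for the K-means initialization.
#' @return Tibble with `smiles`, `cluster` (integer), plus the first two
#'   principal-component coordinates of the similarity rows (`pc1`, `pc2`,
#'   for plotting) and their explained-variance shares as attributes
#'   `explained_var`.
#' @export
cluster_molecules <- function(smiles, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(smiles) > k)
  S <- tanimoto_matrix(smiles)
  km <- withr_seed(seed, stats::kmeans(S, centers = k, nstart = 10L,
                                       iter.max = 50L))
  pc <- stats::prcomp(S, rank. = 2L)
  out <- tibble::tibble(smiles = smiles,
                        cluster = as.integer(km$cluster),
                        pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  attr(out, "explained_var") <-
    (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out
}

#' Leave-one-cluster-out evaluation
#'
#' Clusters the dataset with [cluster_molecules()], then holds out each
#' cluster as a test set once while training on the remainder. Clusters whose
#' held-out part contains a single class are skipped with a warning (their
#' AUC is undefined).
#'
#' @inheritParams cmms_crossval
#' @param n_clusters Number of structural clusters (default 5).
#' @return Tibble with one row per evaluated cluster: `cluster`, `n_test`,
#'   `auc`, `accuracy`, `f1`, `mcc`; cluster assignments are attached as the
#'   `clusters` attribute.
#' @export
cmms_cluster_eval <- function(data, config = cmms_config(), n_clusters = 5L,
                              embeddings = NULL, verbose = FALSE) {
  stopifnot(n_clusters >= 2L)
  cl <- cluster_molecules(data$smiles, k = n_clusters, seed = config$seed)
  rows <- list()
  for (k in seq_len(n_clusters)) {
    te <- cl$cluster == k
    if (length(unique(data$label[te])) < 2L ||
        length(unique(data$label[!te])) < 2L) {
      warning(sprintf("cluster %d skipped: single-class split", k),
              call. = FALSE)
      next
    }
    cfg <- config
    cfg$seed <- config$seed + k
    fit <- cmms_fit(data[!te, , drop = FALSE], cfg, embeddings = embeddings)
    pr <- stats::predict(fit, data[te, , drop = FALSE])
    mt <- evaluate_predictions(dplyr::mutate(pr, label = data$label[te]))
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(cluster = k, n_test = sum(te)), mt[, 1:4])
    if (verbose) {
      message(sprintf("cluster %d (n=%d): AUC %.3f", k, sum(te), mt$auc))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "clusters") <- cl
  out
}

#' Sweep the contrastive loss weight
#'
#' Refits the model for each candidate weight and evaluates on a held-out
#' split, reproducing the conventional grid
#' \{0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2\}.
#'
#' @inheritParams cmms_crossval
#' @param lambdas Numeric vector of weights to try.
#' @param holdout Fraction of molecules held out for evaluation.
#' @return Tibble with one row per lambda and the evaluation metrics.
#' @export
sweep_lambda <- function(data, config = cmms_config(),
                         lambdas = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75,
                                     1, 1.5, 2),
                         holdout = 0.2, embeddings = NULL, verbose = FALSE) {
  n <- nrow(data)
  te <- withr_seed(config$seed,
                   sample.int(n, max(2L, round(holdout * n))))
  rows <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$lambda <- lam
    fit <- cmms_fit(data[-te, , drop = FALSE], cfg, embeddings = embeddings)
    pr <- stats::predict(fit, data[te, , drop = FALSE])
    mt <- evaluate_predictions(dplyr::mutate(pr, label = data$label[te]))
    if (verbose) message(sprintf("lambda %.2f: AUC %.3f", lam, mt$auc))
    dplyr::bind_cols(tibble::tibble(lambda = lam), mt)
  })
  dplyr::bind_rows(rows)
}
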