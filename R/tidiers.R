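# broom-style accessors for fitted models.

#' Tidy a fitted model's training history
#'
#' @param x A `cmms_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `loss_class`,
#'   `loss_contr` and, when a validation set was supplied to [cmms_fit()],
#'   `val_auc` and `val_accuracy`.
#' @method tidy cmms_model
#' @export
tidy.cmms_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), loss = numeric(0)))
  }
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `cmms_model`.
#' @param ... Unused.
#' @return One-row tibble: parameter count, architecture switches, epochs
#'   trained and final losses.
#' @method glance cmms_model
#' @export
glance.cmms_model <- function(x, ...) {
  last <- if (!is.null(x$history) && nrow(x$history) > 0) {
    x$history[nrow(x$history), ]
  } else {
    tibble::tibble(loss = NA_real_, loss_class = NA_real_,
                   loss_contr = NA_real_)
  }
  tibble::tibble(
    n_parameters = length(tree_flatten(x$params)),
    use_sequence = x$config$use_sequence,
    gin_layers = x$config$K,
    heads = x$config$heads,
    lambda = x$config$lambda,
    augment = x$config$augment,
    epochs_trained = if (is.null(x$history)) NA_integer_
                     else nrow(x$history),
    final_loss = last$loss,
    final_loss_class = last$loss_class,
    final_loss_contr = last$loss_contr
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
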