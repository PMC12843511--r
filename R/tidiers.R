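# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PC space
#'
#' One row per component with its explained-variance fraction.
#' @param x A `pc_space`.
#' @param ... Unused.
#' @return Tibble `component`, `explained_variance`, `cumulative`.
#' @export
tidy.pc_space <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 explained_variance = x$explained,
                 cumulative = cumsum(x$explained))
}

#' One-row summary of a fitted PC space
#' @param x A `pc_space`.
#' @param ... Unused.
#' @return Tibble with component count, feature count and total variance
#'   captured.
#' @export
glance.pc_space <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_features = length(x$feature_cols),
                 variance_captured = sum(x$explained))
}

#' Tidy a prediction run
#'
#' The per-(organoid, loop) prediction table with run metadata attached.
#' @param x A `prediction_run`.
#' @param ... Unused.
#' @return Tibble of predictions.
#' @export
tidy.prediction_run <- function(x, ...) {
  out <- x$predictions
  out$model <- x$model
  out$fold_id <- x$fold_id
  out
}

#' One-row summary of a prediction run
#' @param x A `prediction_run`.
#' @param ... Unused.
#' @return Tibble with model, fold, class count, best validation F1 and
#'   test F1.
#' @export
glance.prediction_run <- function(x, ...) {
  te <- x$predictions[x$predictions$partition == "test", ]
  tibble::tibble(model = x$model, fold_id = x$fold_id,
                 n_classes = length(x$classes),
                 shuffled = isTRUE(x$shuffled),
                 best_val_f1 = x$best_val_f1,
                 test_f1 = if (nrow(te))
                   f1_weighted(te$truth, te$pred) else NA_real_)
}

#' Tidy a classifier comparison
#'
#' @param x A `classifier_comparison`.
#' @param ... Unused.
#' @return The comparison tibble (method pairs with raw and Holm-adjusted
#'   p-values).
#' @export
tidy.classifier_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a classifier comparison
#' @param x A `classifier_comparison`.
#' @param ... Unused.
#' @return Tibble with pair count and number of significant pairs at 0.05
#'   after adjustment.
#' @export
glance.classifier_comparison <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_significant = sum(x$p_adj < 0.05))
}
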