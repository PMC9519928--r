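#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ReliefF importance object
#'
#' @param x A [relieff_importance()] result.
#' @param ... Unused.
#' @return A tibble `pcg_id`, `weight`, `rank`, ordered by rank.
#' @method tidy relieff_importance
#' @export
tidy.relieff_importance <- function(x, ...) {
  tibble::tibble(
    pcg_id = names(x$weights)[x$ranking],
    weight = unname(x$weights[x$ranking]),
    rank = seq_along(x$ranking)
  )
}

#' Tidy an SDNE embedding into long format
#'
#' @param x An [train_sdne()] result.
#' @param ... Unused.
#' @return A tibble `node_id`, `dimension`, `value`.
#' @method tidy sdne_embedding
#' @export
tidy.sdne_embedding <- function(x, ...) {
  tibble::as_tibble(x$embedding, rownames = "node_id") |>
    tidyr::pivot_longer(-"node_id", names_to = "dimension",
                        values_to = "value") |>
    dplyr::mutate(dimension = as.integer(gsub("\\D", "", .data$dimension)))
}

#' One-row summary of an SDNE embedding
#'
#' @inheritParams tidy.sdne_embedding
#' @return A tibble with node count, dimension, epochs and first/final loss.
#' @method glance sdne_embedding
#' @export
glance.sdne_embedding <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$embedding), embedding_dim = ncol(x$embedding),
    epochs = length(x$loss), initial_loss = x$loss[1],
    final_loss = x$loss[length(x$loss)]
  )
}

#' Tidy a fitted association model (feature importance)
#'
#' @param x An [train_model()] result.
#' @param ... Unused.
#' @return A tibble `feature`, `importance` sorted descending.
#' @method tidy md_model
#' @export
tidy.md_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  if (is.null(imp)) {
    return(tibble::tibble(feature = x$feature_names,
                          importance = NA_real_))
  }
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a fitted association model
#'
#' @inheritParams tidy.md_model
#' @return A tibble with tree count, feature count and out-of-bag error.
#' @method glance md_model
#' @export
glance.md_model <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_estimators, n_features = x$n_features,
    oob_error = x$forest$prediction.error
  )
}

#' One-row summary of a pipeline fit
#'
#' @param x An [run_pipeline()] result.
#' @param ... Unused.
#' @return The metric report with split bookkeeping columns.
#' @method glance md_pipeline_fit
#' @export
glance.md_pipeline_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$metrics),
    tibble::tibble(split_mode = x$split$mode,
                   n_train_pos = x$manifest$n_train_pos,
                   n_test_pos = x$manifest$n_test_pos)
  )
}
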