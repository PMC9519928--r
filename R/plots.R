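#' Plot the SDNE training loss curve
#'
#' @param object An [train_sdne()] result.
#' @param ... Unused.
#' @return A ggplot of total loss per epoch.
#' @method autoplot sdne_embedding
#' @export
autoplot.sdne_embedding <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "total loss",
                  title = "SDNE training loss") +
    ggplot2::theme_minimal()
}

#' Plot the top ReliefF feature weights
#'
#' @param object A [relieff_importance()] result.
#' @param n_top Number of top-ranked features shown.
#' @param ... Unused.
#' @return A ggplot bar chart of feature weights in rank order.
#' @method autoplot relieff_importance
#' @export
autoplot.relieff_importance <- function(object, n_top = 30, ...) {
  df <- head(tidy(object), n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pcg_id, .data$weight), y = .data$weight
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ReliefF weight",
                  title = sprintf("Top %d PCG features", nrow(df))) +
    ggplot2::theme_minimal()
}

#' ROC curve for a labeled prediction table
#'
#' @param object An `md_predictions` tibble carrying a `label` column.
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUC.
#' @method autoplot md_predictions
#' @export
autoplot.md_predictions <- function(object, ...) {
  if (!"label" %in% names(object)) {
    abort("predictions need a `label` column to draw a ROC curve")
  }
  ord <- order(-object$score)
  y <- as.integer(object$label)[ord]
  df <- tibble::tibble(
    tpr = c(0, cumsum(y) / sum(y)),
    fpr = c(0, cumsum(1 - y) / sum(1 - y))
  )
  a <- auc(object$score, object$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", a)) +
    ggplot2::theme_minimal()
}
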