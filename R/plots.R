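# ggplot2 graphics for fitted objects and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the loss trace of a fitted factorization
#'
#' @param object A `manifold_fit`.
#' @param ... Unused.
#' @return A ggplot of loss against iteration (log10 y scale).
#' @method autoplot manifold_fit
#' @export
autoplot.manifold_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss_trace) - 1L,
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = sprintf("Alternating updates (k = %d, mu = %g, lambda = %g)",
                                  object$k, object$hyper$mu, object$hyper$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot with one boxplot per metric over folds and repeats.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$per_fold |>
    tidyr::pivot_longer(c("rmse", "r2", "pcc"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "held-out value",
                  title = sprintf("%d-fold CV, %d repeat(s)",
                                  object$n_folds, object$n_repeats)) +
    ggplot2::theme_minimal()
}

#' Plot observed against predicted responses for selected drugs
#'
#' @param real A [response_matrix()].
#' @param predicted Aligned `n x m` prediction matrix.
#' @param drugs Drug labels to show (default: first 4).
#' @return A faceted ggplot of observed vs predicted log IC50.
#' @export
plot_drugwise <- function(real, predicted, drugs = NULL) {
  stopifnot(inherits(real, "response_matrix"))
  if (is.null(drugs)) drugs <- utils::head(colnames(real$values), 4)
  df <- purrr::map(drugs, function(d) {
    ok <- real$observed[, d] & !is.na(predicted[, d])
    tibble::tibble(drug = d, observed = real$values[ok, d],
                   predicted = predicted[ok, d])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~drug, scales = "free") +
    ggplot2::labs(x = "observed log IC50", y = "predicted log IC50") +
    ggplot2::theme_minimal()
}
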