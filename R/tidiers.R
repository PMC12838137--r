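#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted kernel mixed model
#'
#' @param x a `kmm_fit`.
#' @param ... unused.
#' @return tibble of variance components: term, estimate (posterior mean),
#'   std.error (posterior SD), ess, and the share of the summed components.
#' @export
tidy.kmm_fit <- function(x, ...) {
  vc <- x$var_components
  tibble::tibble(term = vc$term, estimate = vc$mean, std.error = vc$sd,
                 ess = vc$ess, share = vc$mean / sum(vc$mean))
}

#' @rdname tidy.kmm_fit
#' @return `glance()`: one-row tibble with model label, training size,
#'   number of random terms, residual variance and MCMC settings.
#' @export
glance.kmm_fit <- function(x, ...) {
  err <- x$var_components$mean[grepl("^error", x$var_components$term)]
  tibble::tibble(model = x$spec$model, nobs = nrow(x$fitted),
                 n_terms = length(x$effects), sigma2_error = mean(err),
                 min_ess = min(x$var_components$ess),
                 nIter = x$settings$nIter, burnIn = x$settings$burnIn)
}

#' @export
tidy.selection_report <- function(x, ...) x$per_environment

#' @export
glance.selection_report <- function(x, ...) x$summary

#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' @export
tidy.fst_result <- function(x, ...) {
  tibble::tibble(group1 = rownames(x$fst)[row(x$fst)[upper.tri(x$fst)]],
                 group2 = colnames(x$fst)[col(x$fst)[upper.tri(x$fst)]],
                 fst = x$fst[upper.tri(x$fst)])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot variance-component shares of a fit
#'
#' @param object a `kmm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kmm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term, .data$share),
                                  y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of summed variance components",
                  title = sprintf("Variance decomposition (%s)",
                                  object$spec$model)) +
    ggplot2::theme_minimal()
}

#' Plot per-run prediction abilities of a cross-validation result
#'
#' @param object a `cv_result` from [cv_evaluate()].
#' @param ... unused.
#' @return a ggplot (boxplots of per-run mean r by model and scheme cell).
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- summarise_cv(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$r)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = NULL, y = "prediction ability (Pearson r)") +
    ggplot2::theme_minimal()
}

#' Plot environment clusters in principal-coordinate space
#'
#' @param object a `cluster_assignment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object$coordinates),
                     cluster = factor(object$assignment$cluster))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                  colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("Environment clusters (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot environment-variable importance
#'
#' @param object an `ev_importance`.
#' @param top number of variables shown.
#' @param ... unused.
#' @return a ggplot (per-variable mean scaled gain).
#' @export
autoplot.ev_importance <- function(object, top = 15, ...) {
  d <- head(object$variable_importance, top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable,
                                                     .data$scaled),
                                  y = .data$scaled)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean scaled gain") +
    ggplot2::theme_minimal()
}

#' Plot per-environment selection gains
#'
#' @param object a `selection_report`.
#' @param ... unused.
#' @return a ggplot comparing adapted and overall-top gains per
#'   environment.
#' @export
autoplot.selection_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_environment,
                           c("gain_adapted", "gain_overall"),
                           names_to = "set", values_to = "gain")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$environment, y = .data$gain,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "selection gain (Q/ha)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
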