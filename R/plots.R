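# ggplot2 figures for each result type. Heatmaps keep the input
# parameter order (no clustering of the display).

#' Correlation heatmap
#'
#' Spearman coefficients as a square heatmap in input parameter order;
#' undefined pairs are blank.
#'
#' @param corr A [spearman_matrix()] result.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  pars <- colnames(corr$r)
  df <- tidyr::expand_grid(parameter_1 = pars, parameter_2 = pars)
  df$r <- as.vector(t(corr$r))
  df$parameter_1 <- factor(df$parameter_1, levels = pars)
  df$parameter_2 <- factor(df$parameter_2, levels = rev(pars))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter_1, .data$parameter_2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @export
autoplot.correlation_result <- function(object, ...) {
  plot_correlation_heatmap(object)
}

#' ROC curves for screened parameters
#'
#' One curve per parameter (per model when the screen was stratified),
#' with the chance diagonal.
#'
#' @param screen A [roc_screen()] tibble (with its `roc` list-column).
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(screen) {
  curves <- purrr::map2_dfr(screen$roc, seq_len(nrow(screen)), function(r, i) {
    dplyr::mutate(r$curve, parameter = screen$parameter[i],
                  model = screen$model[i])
  })
  gg <- ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                             colour = .data$parameter)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Parameter") +
    ggplot2::theme_minimal()
  if (any(!is.na(curves$model))) {
    gg <- gg + ggplot2::facet_wrap(ggplot2::vars(.data$model))
  }
  gg
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s: AUC %.3f",
                      if (is.na(object$parameter)) "scores" else object$parameter,
                      object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' PC1-by-PC2 scatter coloured by group
#'
#' @param run A [run_pca()] / [fit_reference_pca()] result.
#' @param table The parameter table the run was fitted on (for group
#'   labels); optional.
#' @return A ggplot object.
#' @export
plot_pca_scatter <- function(run, table = NULL) {
  df <- tibble::tibble(pc1 = run$scores[, 1],
                       pc2 = if (ncol(run$scores) >= 2) run$scores[, 2] else 0)
  if (!is.null(table)) {
    df$group <- table$group[match(rownames(run$scores) %||% run$animal_id,
                                  table$animal_id)] %||% table$group
  } else {
    df$group <- "all"
  }
  pct <- 100 * run$explained_fraction
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pct[1]),
      y = if (length(pct) >= 2) sprintf("PC2 (%.1f%%)", pct[2]) else "PC2",
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pca_run <- function(object, ...) plot_pca_scatter(object, ...)

#' Scree plot of explained variance
#'
#' @param run A `"pca_run"`.
#' @param sd_threshold Reference line for the component-selection rule.
#' @return A ggplot object.
#' @export
plot_scree <- function(run, sd_threshold = 1) {
  df <- glance.pca_run(run)
  ggplot2::ggplot(df, ggplot2::aes(.data$component,
                                   100 * .data$explained_fraction)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$selected), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Principal component", y = "Explained variance (%)") +
    ggplot2::theme_minimal()
}

#' Stacked severity-allocation bars
#'
#' Percentage of each group allocated to each severity cluster, the
#' standard group-comparison figure.
#'
#' @param alloc An [allocation_table()] result.
#' @return A ggplot object.
#' @export
plot_allocation <- function(alloc) {
  df <- alloc$by_group
  df$cluster <- factor(df$cluster, levels = rev(seq_len(alloc$k)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$pct,
                                         fill = .data$cluster)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_viridis_d(direction = -1, name = "Severity\ncluster") +
    ggplot2::labs(x = NULL, y = "Animals (%)") +
    ggplot2::theme_minimal()
  if (any(!is.na(df$model)) && length(unique(df$model)) > 1) {
    gg <- gg + ggplot2::facet_wrap(ggplot2::vars(.data$model), scales = "free_x")
  }
  gg
}

#' @export
autoplot.allocation_result <- function(object, ...) plot_allocation(object)
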