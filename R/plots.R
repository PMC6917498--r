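# ggplot2 displays for the main result types.

#' Plot a model comparison
#'
#' AIC (relative to the best model) and cross-validated MAPE per scheme.
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$table, "scheme", "delta_aic", "mape"),
    c("delta_aic", "mape"),
    names_to = "criterion", values_to = "value"
  )
  d$criterion <- dplyr::recode(d$criterion,
    delta_aic = "ΔAIC (0 = best)", mape = "CV MAPE (%)"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scheme, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(
      title = paste("Model comparison:", object$edge),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot subtype-specific brain-behavior relationships
#'
#' Covariate-adjusted connectivity against covariate-adjusted behavior, one
#' panel color per group, with the robust regression line implied by each
#' group's fit.
#'
#' @param object A `bb_comparison` from [brain_behavior_cor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bb_comparison <- function(object, ...) {
  d <- purrr::imap_dfr(object$fits, function(f, g) {
    dplyr::mutate(f$adjusted, group = g)
  })
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$edge_adj, y = .data$behavior_adj, color = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      title = paste("Connectivity-behavior relationship:", object$edge),
      x = "connectivity (covariate adjusted)",
      y = "behavior (covariate adjusted)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an empirical power result against the analytic power curve
#'
#' @param object A `power_sim` tibble from [empirical_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_sim <- function(object, ...) {
  ds <- seq(0, max(1.5, object$d[1] * 1.5), length.out = 100)
  curve <- tibble(
    d = ds,
    power = vapply(ds, analytic_power, numeric(1),
      n1 = object$n1[1], n2 = object$n2[1], alpha = object$alpha[1]
    )
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$d, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble(d = object$d, power = object$power_hat),
      color = "red", size = 2
    ) +
    ggplot2::labs(
      title = sprintf(
        "Two-sample power, n = %d vs %d (alpha = %g)",
        object$n1[1], object$n2[1], object$alpha[1]
      ),
      x = "Cohen's d", y = "power"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a partial-correlation matrix
#'
#' @param mat Symmetric connectivity matrix (e.g. from
#'   [ridge_partial_cor()]).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_edge_matrix <- function(mat, title = "partial correlations") {
  labels <- colnames(mat) %||% paste0("C", seq_len(ncol(mat)))
  d <- expand.grid(comp_i = labels, comp_j = labels)
  d$value <- as.vector(mat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comp_j, y = .data$comp_i,
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
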