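# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy an edge-wise GLM
#'
#' @param x An `edge_glm` from [fit_edge_glm()].
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.edge_glm <- function(x, ...) {
  cf <- summary(x$fit_full)$coefficients
  tibble(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )
}

#' @rdname tidy.edge_glm
#' @return For `glance()`: a one-row tibble with the omnibus F test,
#'   partial eta squared, fit size and AIC.
#' @export
glance.edge_glm <- function(x, ...) {
  tibble(
    edge = x$edge, statistic = x$statistic,
    df1 = x$df[1], df2 = x$df[2], p_value = x$p_value,
    partial_eta_sq = x$partial_eta_sq, n = x$n,
    rss = x$rss, n_params = x$n_params, aic = gaussian_aic(x)
  )
}

#' Tidy a model comparison
#'
#' @param x A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return Per-scheme tibble with AIC, delta-AIC, support band, and CV MAPE.
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::mutate(x$table, edge = x$edge, .before = 1)
}

#' @rdname tidy.model_comparison
#' @return For `glance()`: one row naming the preferred scheme by AIC and by
#'   CV MAPE and the MAPE reduction (percentage points) over the runner-up.
#' @export
glance.model_comparison <- function(x, ...) {
  tibble(
    edge = x$edge, n = length(x$subject_ids),
    preferred_aic = x$preferred$aic, preferred_mape = x$preferred$mape,
    min_aic = min(x$table$aic), max_delta_aic = max(x$table$delta_aic),
    mape_reduction = x$mape_reduction
  )
}

#' Tidy a robust brain-behavior correlation
#'
#' @param x A `bb_cor` from [robust_partial_cor()].
#' @param ... Unused.
#' @return One-row tibble: `r`, `p_value`, `n`, bootstrap CI bounds,
#'   `n_boot`, `converged`.
#' @export
tidy.bb_cor <- function(x, ...) {
  tibble(
    r = x$r, statistic = x$t, df = x$df, p_value = x$p_value, n = x$n,
    ci_low = x$ci_low, ci_high = x$ci_high, n_boot = x$n_boot,
    n_degenerate = x$n_degenerate, converged = x$converged
  )
}

#' @rdname tidy.bb_cor
#' @export
glance.bb_cor <- function(x, ...) tidy(x)

#' Tidy a brain-behavior group comparison
#'
#' @param x A `bb_comparison` from [brain_behavior_cor()].
#' @param ... Unused.
#' @return The per-group correlation tibble.
#' @export
tidy.bb_comparison <- function(x, ...) x$by_group

#' @rdname tidy.bb_comparison
#' @export
glance.bb_comparison <- function(x, ...) {
  out <- tibble(edge = x$edge, n_groups = nrow(x$by_group))
  if (!is.null(x$difference)) {
    out$z <- x$difference$z
    out$p_value <- x$difference$p_value
  }
  out
}
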