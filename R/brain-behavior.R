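#' Robust linear regression (IRLS with Tukey bisquare weights)
#'
#' Iteratively reweighted least squares starting from the ordinary
#' least-squares solution, with the Tukey bisquare weight function (tuning
#' constant 4.685, i.e. 95 percent Gaussian efficiency) and the robust scale
#' re-estimated each iteration from the MAD of residuals. Iterates until the
#' maximum coefficient change falls below `tol` or `maxit` iterations;
#' non-convergence is flagged and the last iterate returned. With no outliers
#' the solution is numerically close to ordinary least squares.
#'
#' @param response Numeric response vector.
#' @param predictors Numeric matrix or data frame of predictors (an intercept
#'   is added automatically).
#' @param tuning Bisquare tuning constant (default 4.685).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param maxit Maximum IRLS iterations (default 50).
#' @return List: `coefficients` (intercept first), `weights`,
#'   `t_statistics`, `df`, `se`, `converged`, `iterations`.
#' @export
#' @examples
#' x <- seq_len(20)
#' fit <- robust_fit(2 * x, x)
#' fit$coefficients[["x"]] # 2, all weights 1
robust_fit <- function(response, predictors, tuning = 4.685, tol = 1e-8, maxit = 50) {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(x) != n) abort("`response` and `predictors` sizes differ")
  if (n <= ncol(x) + 1) abort("need n > number of predictors + 1")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite inputs")
  design <- cbind(`(Intercept)` = 1, x)
  f <- irls_bisquare_cpp(design, y, tuning, tol, as.integer(maxit))
  coefs <- setNames(as.numeric(f$coefficients), colnames(design))
  se <- setNames(as.numeric(f$se), colnames(design))
  df <- n - ncol(design)
  list(
    coefficients = coefs, weights = as.numeric(f$weights),
    se = se, t_statistics = coefs / se, df = df,
    converged = isTRUE(f$converged), iterations = f$iterations
  )
}

#' Robust-regression partial correlation between an edge and behavior
#'
#' Partial correlation between a connectivity edge and a behavioral score
#' (ADOS social affect total in the study design) controlling for covariates
#' (age at scan), derived from the robust fit of behavior on the edge plus
#' covariates: `r = sign(b) * sqrt(t^2 / (t^2 + df))` with `df = n -
#' predictors - 1`. Also returns the covariate-adjusted scores (edge and
#' behavior each robustly residualized on the covariates) used for plotting.
#'
#' @param edge_values Numeric vector of per-subject edge values.
#' @param behavior Numeric vector of behavior scores.
#' @param covariates Optional numeric matrix / data frame of covariates.
#' @param n_boot Bootstrap resamples for the percentile 95 percent CI
#'   (default 100000, the study's setting); set to 0 to skip.
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `bb_cor`: tibble-like list with `r`, `t`, `df`,
#'   `p_value`, `n`, `ci_low`, `ci_high`, `n_boot`, `n_degenerate`,
#'   `converged`, and an `adjusted` tibble of plotting scores. [tidy()] gives
#'   the one-row summary.
#' @export
robust_partial_cor <- function(edge_values, behavior, covariates = NULL,
                               n_boot = 0, seed = 1, conf_level = 0.95) {
  keep <- complete.cases(edge_values, behavior,
    if (is.null(covariates)) rep(0, length(edge_values)) else covariates
  )
  x <- edge_values[keep]
  y <- behavior[keep]
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete subjects")
  if (sd(y) == 0 || sd(x) == 0) abort("behavior and edge values must be non-constant")

  preds <- if (is.null(z)) cbind(edge = x) else cbind(edge = x, z)
  fit <- robust_fit(y, preds)
  t <- fit$t_statistics[["edge"]]
  df <- fit$df
  r <- sign(fit$coefficients[["edge"]]) * sqrt(t^2 / (t^2 + df))

  ci <- c(NA_real_, NA_real_)
  ndeg <- 0L
  if (n_boot > 0) {
    ci_out <- bootstrap_ci(x, y, covariates = z, n_boot = n_boot, seed = seed,
      conf_level = conf_level)
    ci <- c(ci_out$ci_low, ci_out$ci_high)
    ndeg <- ci_out$n_degenerate
  }

  adjusted <- if (is.null(z)) {
    tibble(edge_adj = x - mean(x), behavior_adj = y - mean(y))
  } else {
    fx <- robust_fit(x, z)
    fy <- robust_fit(y, z)
    tibble(
      edge_adj = x - drop(cbind(1, z) %*% fx$coefficients),
      behavior_adj = y - drop(cbind(1, z) %*% fy$coefficients)
    )
  }

  structure(
    list(
      r = unname(r), t = unname(t), df = df,
      p_value = 2 * pt(-abs(t), df), n = n,
      ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
      n_degenerate = ndeg, converged = fit$converged,
      conf_level = conf_level, adjusted = adjusted
    ),
    class = "bb_cor"
  )
}

#' @export
print.bb_cor <- function(x, ...) {
  cat(sprintf(
    "<bb_cor> r = %.3f, p = %.3g, n = %d%s\n", x$r, x$p_value, x$n,
    if (x$n_boot > 0) {
      sprintf(", %d%% CI [%.2f, %.2f] (%s resamples)",
        round(100 * x$conf_level), x$ci_low, x$ci_high,
        format(x$n_boot, big.mark = ","))
    } else ""
  ))
  invisible(x)
}

#' Bootstrap confidence interval for the robust partial correlation
#'
#' Percentile interval over subject-level resamples with replacement; each
#' resample recomputes the full robust-regression partial correlation.
#' Degenerate resamples (constant edge or behavior) are redrawn and counted.
#'
#' @inheritParams robust_partial_cor
#' @param n_boot Number of resamples (at least 100; study default 100000).
#' @return List: `ci_low`, `ci_high`, `boot_median`, `n_degenerate`.
#' @export
bootstrap_ci <- function(edge_values, behavior, covariates = NULL,
                         n_boot = 100000, seed = 1, conf_level = 0.95) {
  if (n_boot < 100) abort("`n_boot` must be at least 100")
  x <- as.numeric(edge_values)
  y <- as.numeric(behavior)
  if (length(x) < 5) abort("need at least 5 subjects")
  z <- if (is.null(covariates)) {
    matrix(0, length(x), 0)
  } else {
    as.matrix(covariates)
  }
  out <- with_local_seed(
    seed,
    boot_rpcor_cpp(x, y, z, as.integer(n_boot), 4.685, 1e-8, 50L)
  )
  rs <- out$r[is.finite(out$r)]
  alpha <- (1 - conf_level) / 2
  qs <- unname(quantile(rs, c(alpha, 1 - alpha), type = 7))
  list(
    ci_low = qs[1], ci_high = qs[2], boot_median = median(rs),
    n_degenerate = out$n_degenerate
  )
}

#' Subtype-specific brain-behavior correlations for one edge
#'
#' Runs [robust_partial_cor()] within each requested group (dropping subjects
#' with missing behavior, with a count) and, when exactly two groups are
#' given, tests the difference in correlation strength with
#' [compare_correlations()].
#'
#' @param edges Long edge tibble from [compute_edges()].
#' @param subjects Subjects tibble.
#' @param edge Edge name, e.g. `"DMN-OTC"`.
#' @param groups Character vector of group labels (default the two ASD
#'   subtypes).
#' @param behavior Column of `subjects` holding the behavior score.
#' @param covariates Covariate columns of `subjects` (default age at scan).
#' @param n_boot,seed Bootstrap settings per group.
#' @return Object of class `bb_comparison`: per-group tibble `by_group`, the
#'   fitted `bb_cor` objects, and `difference` (z test between the first two
#'   groups, when applicable).
#' @export
brain_behavior_cor <- function(edges, subjects, edge,
                               groups = c("GeoPref ASD", "nonGeo ASD"),
                               behavior = "ados_sa",
                               covariates = "age_scan_months",
                               n_boot = 100000, seed = 1) {
  subjects <- as_tibble(subjects)
  e <- edges[edges$edge == edge, c("subject_id", "value")]
  if (nrow(e) == 0) abort(sprintf("edge '%s' not found", edge))
  fits <- list()
  rows <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    sub <- dplyr::inner_join(subjects[subjects$group == g, , drop = FALSE], e,
      by = "subject_id"
    )
    n_missing <- sum(is.na(sub[[behavior]]))
    fit <- robust_partial_cor(
      sub$value, sub[[behavior]],
      covariates = sub[, covariates, drop = FALSE],
      n_boot = n_boot, seed = seed + i
    )
    fits[[g]] <- fit
    rows[[g]] <- dplyr::mutate(tidy(fit), group = g, n_missing_behavior = n_missing,
      .before = 1)
  }
  difference <- NULL
  if (length(groups) >= 2) {
    f1 <- fits[[groups[1]]]
    f2 <- fits[[groups[2]]]
    difference <- compare_correlations(f1$r, f1$n, f2$r, f2$n)
  }
  structure(
    list(edge = edge, by_group = dplyr::bind_rows(rows), fits = fits,
      difference = difference),
    class = "bb_comparison"
  )
}

#' @export
print.bb_comparison <- function(x, ...) {
  cat("<bb_comparison> edge", x$edge, "\n")
  print(x$by_group)
  if (!is.null(x$difference)) {
    cat(sprintf(
      "difference in correlation strength: z = %.2f, p = %.3g\n",
      x$difference$z, x$difference$p_value
    ))
  }
  invisible(x)
}

#' Test the difference between two independent correlations
#'
#' Fisher z test: `z = (arctanh(r1) - arctanh(r2)) / sqrt(1/(n1-3) +
#' 1/(n2-3))` with a two-sided normal p-value.
#'
#' @param r1,r2 Correlations (`|r| < 1`).
#' @param n1,n2 Sample sizes (each greater than 3).
#' @return Tibble: `z`, `p_value`.
#' @export
#' @examples
#' compare_correlations(-0.78, 16, 0.06, 62)
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("correlations must satisfy |r| < 1")
  if (n1 <= 3 || n2 <= 3) abort("need n > 3 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}
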