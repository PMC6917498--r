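#' Edge-wise general linear model with group and covariates
#'
#' Fits one connectivity edge (the per-subject Fisher-z partial correlation)
#' as the dependent variable of an ordinary least-squares GLM with the design
#' labeling of interest plus age-at-scan and sex covariates. The omnibus test
#' compares the full model against the model without the group term (for the
#' transdiagnostic scheme, without the continuous fixation predictor), giving
#' e.g. `F(3, 189)` for four groups plus age and sex on 195 subjects.
#'
#' @param edges Long edge tibble from [compute_edges()].
#' @param design A [build_design()] labeling.
#' @param edge Edge name, e.g. `"DMN-OTC"`.
#' @param covariates Covariate columns of the design data (default age at
#'   scan and sex). Use `character(0)` for none.
#' @return Object of class `edge_glm`: omnibus `statistic` (F), `df`,
#'   `p_value`, `partial_eta_sq` (`SS_group / (SS_group + SS_resid)`), `rss`,
#'   `n_params`, `n`, plus the underlying [lm] fits. [tidy()] returns the
#'   coefficient table, [glance()] the one-row summary.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 2))
#' edges <- compute_edges(cohort)
#' fit <- fit_edge_glm(edges, build_design(cohort$subjects, "case_control"), "DMN-OTC")
#' glance(fit)
fit_edge_glm <- function(edges, design, edge,
                         covariates = c("age_scan_months", "sex")) {
  stopifnot(inherits(design, "geo_design"))
  df <- edge_design_frame(edges, design, edge, covariates)
  predictor <- if (design$scheme == "transdiagnostic") "pct_geo" else "label"
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- lm(as.formula(paste("value ~", predictor, "+", rhs_red)), data = df)
  reduced <- lm(as.formula(paste("value ~", rhs_red)), data = df)
  if (any(is.na(coef(full)))) abort("rank-deficient design for this edge")
  n <- nrow(df)
  n_params <- length(coef(full))
  if (n <= n_params) abort("too few subjects for the requested design")

  rss_full <- sum(residuals(full)^2)
  rss_red <- sum(residuals(reduced)^2)
  df1 <- n_params - length(coef(reduced))
  df2 <- n - n_params
  ss_group <- rss_red - rss_full
  f <- (ss_group / df1) / (rss_full / df2)
  structure(
    list(
      edge = edge, scheme = design$scheme, n = n,
      statistic = f, df = c(df1, df2),
      p_value = pf(f, df1, df2, lower.tail = FALSE),
      partial_eta_sq = ss_group / (ss_group + rss_full),
      rss = rss_full, n_params = n_params,
      fit_full = full, fit_reduced = reduced, data = df
    ),
    class = "edge_glm"
  )
}

edge_design_frame <- function(edges, design, edge, covariates) {
  e <- edges[edges$edge == edge, , drop = FALSE]
  if (nrow(e) == 0) abort(sprintf("edge '%s' not found in `edges`", edge))
  df <- dplyr::inner_join(
    dplyr::select(e, "subject_id", "value"),
    design$data,
    by = "subject_id"
  )
  if (nrow(df) == 0) abort("no overlap between edge vectors and design subjects")
  bad <- setdiff(covariates, names(df))
  if (length(bad)) abort(paste0("covariates not in design data: ", paste(bad, collapse = ", ")))
  df
}

#' Omnibus group tests across all edges with FDR control
#'
#' Runs [fit_edge_glm()] for every edge in the family and applies
#' Benjamini-Hochberg FDR across edges.
#'
#' @inheritParams fit_edge_glm
#' @param q FDR level (default 0.05).
#' @param family Optional character vector restricting the edge family;
#'   defaults to all edges present.
#' @return Tibble with one row per edge: `edge`, `statistic`, `df1`, `df2`,
#'   `p_value`, `partial_eta_sq`, `q_value`, `discovered`.
#' @export
edgewise_glm <- function(edges, design, covariates = c("age_scan_months", "sex"),
                         q = 0.05, family = NULL) {
  fam <- family %||% unique(edges$edge)
  res <- purrr::map_dfr(fam, function(e) glance(fit_edge_glm(edges, design, e, covariates)))
  adj <- fdr_bh(res$p_value, q = q)
  dplyr::mutate(res, q_value = adj$q_value, discovered = adj$discovered)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the discovery mask
#' at level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble: `p_value`, `q_value`, `discovered`.
#' @export
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.9))
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) abort("`p_values` is empty")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = adj, discovered = adj <= q)
}

#' Freedman-Lane permutation test for a two-group contrast
#'
#' Covariate-adjusted permutation test of a group difference on one edge. The
#' observed statistic is the group coefficient from the full OLS model
#' `value ~ group + covariates`. Permutation follows Freedman-Lane: the edge
#' is residualized on the covariates under the reduced model, residuals are
#' permuted and added back to the reduced-model fit, and the full model is
#' refit. The two-sided p-value uses the add-one convention
#' `(1 + #permuted |stat| >= observed |stat|) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param value Numeric edge values.
#' @param label Two-level group labels (character or factor).
#' @param covariates Optional data frame / matrix of covariates.
#' @param n_perm Number of permutations (default 10000, the study's setting;
#'   at least 100).
#' @param seed Integer seed.
#' @return One-row tibble: `group_a`, `group_b`, `estimate` (adjusted group
#'   coefficient, `group_b - group_a`), `cohens_d`, `perm_p`, `n_perm`.
#' @export
permutation_pairwise <- function(value, label, covariates = NULL,
                                 n_perm = 10000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm", lower = 100)
  g <- factor(label)
  if (nlevels(g) != 2) abort("`label` must have exactly two levels")
  if (any(table(g) < 2)) abort("each group needs at least 2 subjects")
  n <- length(value)
  if (length(g) != n) abort("`value` and `label` lengths differ")

  z <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(1, n, 1)
  } else {
    model.matrix(~., data = as.data.frame(covariates))
  }
  x <- cbind(z, gb = as.numeric(g == levels(g)[2]))
  qz <- qr(z)
  qx <- qr(x)
  if (qx$rank < ncol(x)) abort("rank-deficient permutation design")

  fitted_r <- qr.fitted(qz, value)
  resid_r <- qr.resid(qz, value)
  obs <- qr.coef(qx, value)[ncol(x)]

  perm_idx <- with_local_seed(seed, replicate(n_perm, sample.int(n)))
  ystar <- fitted_r + matrix(resid_r[perm_idx], n, n_perm)
  stat <- qr.coef(qx, ystar)[ncol(x), ]
  p <- (1 + sum(abs(stat) >= abs(obs))) / (n_perm + 1)

  tibble(
    group_a = levels(g)[1], group_b = levels(g)[2],
    estimate = unname(obs),
    cohens_d = cohens_d(value[g == levels(g)[2]], value[g == levels(g)[1]]),
    perm_p = p, n_perm = n_perm
  )
}

#' All pairwise group comparisons on one edge, FDR-corrected
#'
#' Follow-up analysis for edges surviving the omnibus FDR threshold: runs
#' [permutation_pairwise()] for every pair of design labels and corrects the
#' permutation p-values with FDR across the pairwise family.
#'
#' @inheritParams fit_edge_glm
#' @param n_perm,seed Passed to [permutation_pairwise()] (each pair gets a
#'   distinct derived seed).
#' @param q FDR level within the pairwise family.
#' @return Tibble with one row per group pair, including `fdr_q` and
#'   `discovered`.
#' @export
pairwise_group_tests <- function(edges, design, edge,
                                 covariates = c("age_scan_months", "sex"),
                                 n_perm = 10000, seed = 1, q = 0.05) {
  stopifnot(inherits(design, "geo_design"), design$scheme != "transdiagnostic")
  df <- edge_design_frame(edges, design, edge, covariates)
  labs <- sort(unique(df$label))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  res <- purrr::imap_dfr(pairs, function(pr, i) {
    sel <- df$label %in% pr
    permutation_pairwise(
      df$value[sel], df$label[sel],
      covariates = df[sel, covariates, drop = FALSE],
      n_perm = n_perm, seed = seed + i
    )
  })
  adj <- fdr_bh(res$perm_p, q = q)
  dplyr::mutate(res, edge = edge, fdr_q = adj$q_value, discovered = adj$discovered)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled SD using `(n - 2)`-weighted
#' variances; no small-sample correction.
#'
#' @param x,y Numeric samples (each of size at least 2).
#' @return Standardized difference (positive when `x` has the larger mean).
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5)) # -2
cohens_d <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each sample needs at least 2 observations")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) abort("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction, `df = (r - 1)(c - 1)`;
#' used for the male/female-by-group demographic balance check.
#'
#' @param table Matrix of non-negative integer counts with positive margins.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' sex_by_group <- rbind(
#'   c(27, 4), c(11, 5), c(49, 13), c(10, 5), c(8, 8), c(37, 18)
#' )
#' contingency_chi2(sex_by_group) # chi2 = 9.89, df = 5
contingency_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("contingency table has a zero margin")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way ANOVA F test (e.g. for age-at-scan or head-motion
#' balance across groups).
#'
#' @param values Numeric response.
#' @param labels Group labels (at least 2 groups, each of size at least 2).
#' @return Tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
oneway_anova <- function(values, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 observations")
  if (var(values) == 0) abort("zero total variance: ANOVA undefined")
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p_value = unname(ht$p.value)
  )
}
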