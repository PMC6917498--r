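#' Gaussian AIC of an ordinary least-squares fit
#'
#' `AIC = n [ln(2 pi) + ln(rss / n) + 1] + 2 (n_params + 1)`, the full Gaussian
#' log-likelihood convention with the residual variance counted as a
#' parameter (so values match [stats::AIC()] on the same [lm] fit). Differences
#' between models fitted to identical data are invariant to the additive
#' constant.
#'
#' @param fit An `edge_glm` or [lm] object, or (default method) the residual
#'   sum of squares as a bare number.
#' @param n,n_params Sample size and number of mean parameters (default method
#'   only).
#' @param ... Unused.
#' @return AIC value.
#' @export
#' @examples
#' gaussian_aic(10, n = 10, n_params = 2) # 10 * (log(2*pi) + 1) + 6
gaussian_aic <- function(fit, ...) UseMethod("gaussian_aic")

#' @rdname gaussian_aic
#' @export
gaussian_aic.default <- function(fit, n, n_params, ...) {
  rss <- fit
  check_number(rss, "rss")
  if (rss <= 0) abort("`rss` must be positive")
  n <- check_count(n, "n")
  n_params <- check_count(n_params, "n_params")
  n * (log(2 * pi) + log(rss / n) + 1) + 2 * (n_params + 1)
}

#' @rdname gaussian_aic
#' @export
gaussian_aic.edge_glm <- function(fit, ...) {
  gaussian_aic(fit$rss, n = fit$n, n_params = fit$n_params)
}

#' @rdname gaussian_aic
#' @export
gaussian_aic.lm <- function(fit, ...) {
  gaussian_aic(sum(residuals(fit)^2),
    n = length(residuals(fit)),
    n_params = length(coef(fit))
  )
}

#' Delta-AIC with support interpretation bands
#'
#' `delta_i = AIC_i - min(AIC)`. Support labels follow the usual
#' interpretation bands: `delta <= 2` "equivalent" (strong support for being
#' equally good), `4 <= delta <= 7` "considerably less support", `delta > 7`
#' "essentially none", otherwise "intermediate".
#'
#' @param aics Numeric vector of at least two finite AIC values.
#' @param labels Optional model names.
#' @return Tibble: `model`, `aic`, `delta_aic`, `support`.
#' @export
#' @examples
#' delta_aic(c(-51.32, -47.60)) # delta 0 and 3.72
delta_aic <- function(aics, labels = NULL) {
  if (length(aics) < 2 || any(!is.finite(aics))) {
    abort("`aics` must hold at least two finite values")
  }
  d <- aics - min(aics)
  support <- dplyr::case_when(
    d <= 2 ~ "equivalent",
    d >= 4 & d <= 7 ~ "considerably less support",
    d > 7 ~ "essentially none",
    TRUE ~ "intermediate"
  )
  tibble(
    model = labels %||% paste0("model", seq_along(aics)),
    aic = aics, delta_aic = d, support = support
  )
}

# Stratified fold assignment: subjects are shuffled within strata, strata are
# concatenated, and fold ids cycle through the concatenation, so fold sizes
# differ by at most one both globally and within each stratum.
make_folds <- function(n, k = 5, strata = NULL, seed = 1) {
  k <- check_count(k, "k", lower = 2)
  if (n < 2 * k) abort("need n >= 2 * k observations for k-fold CV")
  strata <- strata %||% rep(1L, n)
  ord <- with_local_seed(seed, order(as.integer(factor(strata)), runif(n)))
  folds <- integer(n)
  folds[ord] <- rep(seq_len(k), length.out = n)
  folds
}

#' k-fold cross-validated mean absolute percentage error
#'
#' Fits the model on each training split and scores held-out subjects with
#' `MAPE = mean(|(A_i - P_i) / A_i|) * 100`, where `A_i` is the actual and
#' `P_i` the predicted held-out value; the average across folds is reported.
#' Held-out actuals of exactly zero leave the term undefined; such terms are
#' excluded and counted (`n_excluded`). Because connectivity edge values sit
#' near zero, MAPE magnitudes well above 100 are expected and meaningful only
#' comparatively.
#'
#' @param data Data frame containing the response and predictors.
#' @param formula Model formula for [lm].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment (ignored when `folds` is given).
#' @param folds Optional precomputed fold assignment (integer vector), e.g. to
#'   reuse identical folds across competing models.
#' @param strata Optional stratification labels for the fold assignment.
#' @return List with `per_fold` (tibble `fold`, `mape`, `n_test`,
#'   `n_excluded`), `mean_mape`, and the `folds` vector used.
#' @export
kfold_mape <- function(data, formula, k = 5, seed = 1, folds = NULL, strata = NULL) {
  n <- nrow(data)
  folds <- folds %||% make_folds(n, k = k, strata = strata, seed = seed)
  if (length(folds) != n) abort("`folds` must assign every row")
  response <- all.vars(formula)[1]
  per_fold <- purrr::map_dfr(sort(unique(folds)), function(f) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    fit <- lm(formula, data = train)
    if (any(is.na(coef(fit)))) abort("design not estimable in a training split")
    actual <- test[[response]]
    pred <- predict(fit, newdata = test)
    keep <- actual != 0
    tibble(
      fold = f,
      mape = mean(abs((actual[keep] - pred[keep]) / actual[keep])) * 100,
      n_test = length(actual), n_excluded = sum(!keep)
    )
  })
  list(per_fold = per_fold, mean_mape = mean(per_fold$mape), folds = folds)
}

#' Compare case-control, subtype and transdiagnostic models on one edge
#'
#' Fits every requested scheme to the identical subject set (subjects lacking
#' eye tracking are dropped from all schemes whenever any scheme needs eye
#' tracking, so AICs are comparable), then reports per-scheme AIC, delta-AIC
#' with support bands, and 5-fold cross-validated MAPE computed with
#' bit-identical fold assignments across schemes.
#'
#' @param edges Long edge tibble from [compute_edges()].
#' @param subjects Subjects tibble.
#' @param edge Edge name, e.g. `"DMN-OTC"`.
#' @param schemes Design schemes to compare (see [build_design()]).
#' @param covariates Covariates used in every scheme.
#' @param k Number of CV folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return Object of class `model_comparison`; [tidy()] gives the per-scheme
#'   table, [glance()] the preferred scheme by each criterion and the MAPE
#'   reduction (percentage points) of the best over the runner-up model.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 3))
#' edges <- compute_edges(cohort)
#' cmp <- compare_models(edges, cohort$subjects, "DMN-OTC", seed = 1)
#' tidy(cmp)
compare_models <- function(edges, subjects, edge,
                           schemes = c("case_control", "subtype", "transdiagnostic"),
                           covariates = c("age_scan_months", "sex"),
                           k = 5, seed = 1) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (anyDuplicated(schemes)) abort("duplicated schemes")
  common <- as_tibble(subjects)
  if (any(schemes %in% c("subtype", "transdiagnostic"))) {
    common <- common[!is.na(common$pct_geo), , drop = FALSE]
  }
  designs <- lapply(setNames(schemes, schemes), function(s) build_design(common, s))
  id_sets <- lapply(designs, function(d) sort(d$data$subject_id))
  if (length(unique(id_sets)) != 1) {
    abort("schemes ended up on different subject sets; AICs would be incomparable")
  }

  # identical folds for every scheme, stratified by the finest labeling
  strata_design <- tryCatch(build_design(common, "subtype"),
    error = function(e) build_design(common, "case_control")
  )
  strata <- strata_design$data$label[match(id_sets[[1]], strata_design$data$subject_id)]

  rows <- list()
  per_fold <- list()
  folds <- NULL
  for (s in schemes) {
    d <- designs[[s]]
    df <- edge_design_frame(edges, d, edge, covariates)
    df <- df[match(id_sets[[1]], df$subject_id), , drop = FALSE]
    predictor <- if (s == "transdiagnostic") "pct_geo" else "label"
    rhs <- paste(c(predictor, covariates), collapse = " + ")
    form <- as.formula(paste("value ~", rhs))
    fit <- lm(form, data = df)
    if (any(is.na(coef(fit)))) abort(sprintf("rank-deficient design under scheme '%s'", s))
    folds <- folds %||% make_folds(nrow(df), k = k, strata = strata, seed = seed)
    cv <- kfold_mape(df, form, k = k, folds = folds)
    rows[[s]] <- tibble(
      scheme = s, n = nrow(df), n_params = length(coef(fit)),
      rss = sum(residuals(fit)^2), aic = gaussian_aic(fit),
      mape = cv$mean_mape
    )
    per_fold[[s]] <- dplyr::mutate(cv$per_fold, scheme = s, .before = 1)
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) > 1) {
    da <- delta_aic(tab$aic, labels = tab$scheme)
    tab$delta_aic <- da$delta_aic
    tab$support <- da$support
  } else {
    tab$delta_aic <- 0
    tab$support <- "equivalent"
  }
  tab$delta_mape <- tab$mape - min(tab$mape)

  structure(
    list(
      edge = edge, table = tab,
      per_fold = dplyr::bind_rows(per_fold), folds = folds,
      preferred = list(
        aic = tab$scheme[which.min(tab$aic)],
        mape = tab$scheme[which.min(tab$mape)]
      ),
      mape_reduction = if (nrow(tab) > 1) sort(tab$mape)[2] - min(tab$mape) else 0,
      subject_ids = id_sets[[1]]
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> edge", x$edge, "on", length(x$subject_ids), "subjects\n")
  print(x$table)
  cat(
    "preferred by AIC:", x$preferred$aic,
    "| by CV MAPE:", x$preferred$mape,
    sprintf("(MAPE reduction %.2f points)\n", x$mape_reduction)
  )
  invisible(x)
}
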