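test_that("gaussian AIC matches the closed form and stats::AIC", {
  expect_equal(gaussian_aic(10, n = 10, n_params = 2),
    10 * (log(2 * pi) + 1) + 6,
    tolerance = 1e-12
  )
  expect_equal(gaussian_aic(10, n = 10, n_params = 2), 34.3790, tolerance = 1e-4)
  set.seed(31)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  fit <- lm(y ~ x1 + x2, data = d)
  expect_equal(gaussian_aic(fit), AIC(fit), tolerance = 1e-10)
  expect_error(gaussian_aic(0, n = 10, n_params = 2), "positive")
  # adding a pure-noise predictor changes AIC exactly as an independent refit says
  fit0 <- lm(y ~ x1, data = d)
  expect_equal(
    gaussian_aic(fit) - gaussian_aic(fit0), AIC(fit) - AIC(fit0),
    tolerance = 1e-10
  )
})

test_that("delta-AIC reproduces the study's worked examples with support bands", {
  r <- delta_aic(c(-51.32, -47.60))
  expect_equal(r$delta_aic, c(0, 3.72))
  expect_equal(r$support, c("equivalent", "intermediate"))

  r <- delta_aic(c(-87.72, -74.63))
  expect_equal(r$delta_aic, c(0, 13.09))
  expect_equal(r$support[2], "essentially none")

  r <- delta_aic(c(-89.54, -87.72))
  expect_equal(r$delta_aic, c(0, 1.82))
  expect_equal(r$support, c("equivalent", "equivalent"))

  expect_equal(delta_aic(c(5, 5))$support, c("equivalent", "equivalent"))
  expect_equal(delta_aic(c(0, 5))$support[2], "considerably less support")

  # invariance to an additive constant
  a <- delta_aic(c(-10, -3, 4))
  b <- delta_aic(c(-10, -3, 4) + 123.456)
  expect_equal(a$delta_aic, b$delta_aic)
  expect_equal(a$support, b$support)
  expect_error(delta_aic(c(1, NA)), "finite")
  expect_error(delta_aic(3), "at least two")
})

test_that("cross-validated MAPE follows its definition", {
  # perfect predictions give zero error
  d <- data.frame(y = 1:20, x = 1:20)
  cv <- kfold_mape(d, y ~ x, k = 5, seed = 1)
  expect_equal(cv$mean_mape, 0, tolerance = 1e-10)
  expect_equal(nrow(cv$per_fold), 5)

  # independent re-computation with plain loops
  set.seed(32)
  d <- data.frame(y = rnorm(30, 5), x = rnorm(30))
  folds <- make_folds(30, k = 5, seed = 2)
  cv <- kfold_mape(d, y ~ x, folds = folds)
  manual <- sapply(1:5, function(f) {
    fit <- lm(y ~ x, data = d[folds != f, ])
    a <- d$y[folds == f]
    p <- predict(fit, newdata = d[folds == f, , drop = FALSE])
    mean(abs((a - p) / a)) * 100
  })
  expect_equal(cv$per_fold$mape, unname(manual), tolerance = 1e-10)
  expect_equal(cv$mean_mape, mean(manual), tolerance = 1e-10)

  # determinism under the same seed
  cv2 <- kfold_mape(d, y ~ x, k = 5, seed = 7)
  cv3 <- kfold_mape(d, y ~ x, k = 5, seed = 7)
  expect_identical(cv2$per_fold, cv3$per_fold)

  # zero actuals are excluded with a count
  d0 <- data.frame(y = c(0, 2:20), x = 1:20)
  cv0 <- kfold_mape(d0, y ~ 1, k = 5, seed = 3)
  expect_equal(sum(cv0$per_fold$n_excluded), 1)
})

test_that("fold assignment is balanced and stratified", {
  f <- make_folds(53, k = 5, seed = 4)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  strata <- rep(c("a", "b", "c"), length.out = 53)
  fs <- make_folds(53, k = 5, strata = strata, seed = 4)
  expect_true(max(table(fs)) - min(table(fs)) <= 1)
  # every stratum appears in (almost) every training split
  for (k in 1:5) {
    expect_setequal(unique(strata[fs != k]), c("a", "b", "c"))
  }
  expect_error(make_folds(8, k = 5), "n >= 2 \\* k")
})

test_that("compare_models fits all schemes on identical subjects with shared folds", {
  cohort <- generate_cohort(cohort_config(seed = 8))
  edges <- compute_edges(cohort)
  cmp <- compare_models(edges, cohort$subjects, "DMN-OTC", seed = 5)

  expect_equal(length(cmp$subject_ids), 164) # eye-tracked subjects only
  expect_equal(sum(cmp$table$delta_aic == 0), 1)
  expect_true(all(cmp$table$n == 164))
  expect_true(all(cmp$table$mape >= 0))
  # fold sizes differ by at most one and folds are shared across schemes
  expect_true(max(table(cmp$folds)) - min(table(cmp$folds)) <= 1)
  per_scheme_folds <- split(cmp$per_fold$n_test, cmp$per_fold$scheme)
  expect_true(length(unique(per_scheme_folds)) == 1)

  # single scheme: trivially preferred
  one <- compare_models(edges, cohort$subjects, "DMN-OTC",
    schemes = "case_control", seed = 5
  )
  expect_equal(one$table$delta_aic, 0)

  # deterministic under identical seed
  cmp2 <- compare_models(edges, cohort$subjects, "DMN-OTC", seed = 5)
  expect_identical(cmp$table, cmp2$table)

  expect_error(
    compare_models(edges, cohort$subjects, "DMN-XXX", seed = 5),
    "not found"
  )
})

test_that("tidy and glance expose the comparison table", {
  cohort <- generate_cohort(small_config(seed = 6))
  edges <- compute_edges(cohort)
  cmp <- compare_models(edges, cohort$subjects, "DMN-OTC", k = 3, seed = 1)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("edge", "scheme", "aic", "delta_aic", "support", "mape") %in% names(td)))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_true(gl$preferred_aic %in% cmp$table$scheme)
  expect_equal(gl$mape_reduction, sort(cmp$table$mape)[2] - min(cmp$table$mape))
})
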