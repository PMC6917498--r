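test_that("robust fit recovers exact linear data with unit weights", {
  x <- seq_len(30)
  fit <- robust_fit(2 * x, x)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-8)
  expect_true(all(fit$weights == 1))
  expect_true(fit$converged)
})

test_that("robust fit resists a gross outlier better than least squares", {
  set.seed(41)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, 0, 0.2)
  y[7] <- 40
  robust <- robust_fit(y, x)$coefficients["x"]
  ols <- coef(lm(y ~ x))["x"]
  expect_lt(abs(robust - 2), abs(ols - 2))
  # the outlier ends up with (near) zero weight
  expect_lt(robust_fit(y, x)$weights[7], 0.01)
})

test_that("robust fit matches the MASS rlm oracle on clean and dirty data", {
  set.seed(42)
  x <- cbind(a = rnorm(60), b = rnorm(60))
  y <- 1 + 0.5 * x[, 1] - 0.3 * x[, 2] + rnorm(60, 0, 0.5)
  y[3] <- 15
  ours <- robust_fit(y, x)$coefficients
  oracle <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(unname(ours), unname(coef(oracle)), tolerance = 0.02)
  # without outliers both agree with ordinary least squares
  y2 <- 1 + 0.5 * x[, 1] + rnorm(60, 0, 1e-4)
  expect_equal(
    unname(robust_fit(y2, x[, 1])$coefficients),
    unname(coef(lm(y2 ~ x[, 1]))),
    tolerance = 1e-3
  )
})

test_that("null robust slopes have central-t statistics", {
  set.seed(43)
  ts <- replicate(300, robust_fit(rnorm(40), rnorm(40))$t_statistics[2])
  expect_gt(stats::ks.test(ts, "pt", df = 38)$p.value, 0.01)
})

test_that("robust partial correlation recovers a generating correlation", {
  set.seed(44)
  edge <- rnorm(200)
  behavior <- -0.8 * edge + sqrt(1 - 0.64) * rnorm(200)
  r <- robust_partial_cor(edge, behavior)
  expect_lt(abs(r$r - (-0.8)), 0.05)
  expect_lt(r$p_value, 1e-10)

  # independence: |r| small with high probability
  r0 <- robust_partial_cor(rnorm(200), rnorm(200))
  expect_lt(abs(r0$r), 0.2)

  # a shared covariate explains both: partialling removes the association
  age <- rnorm(200)
  r2 <- robust_partial_cor(age + rnorm(200, 0, 0.05), age + rnorm(200, 0, 0.05),
    covariates = age
  )
  expect_lt(abs(r2$r), 0.15)

  expect_error(robust_partial_cor(rnorm(4), rnorm(4)), "at least 5")
  expect_error(robust_partial_cor(rnorm(10), rep(1, 10)), "non-constant")
})

test_that("bootstrap intervals are ordered, reproducible and honest about resamples", {
  set.seed(45)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  ci <- bootstrap_ci(x, y, n_boot = 500, seed = 9)
  expect_lte(ci$ci_low, ci$ci_high)
  ci2 <- bootstrap_ci(x, y, n_boot = 500, seed = 9)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(x, y, n_boot = 50), "at least 100")
  # the point estimate falls inside its own interval
  r <- robust_partial_cor(x, y)$r
  expect_gte(r, ci$ci_low - 0.05)
  expect_lte(r, ci$ci_high + 0.05)
})

test_that("contamination moves the robust correlation less than the plain one", {
  set.seed(46)
  deltas <- replicate(15, {
    n <- 80
    edge <- rnorm(n)
    behavior <- -0.6 * edge + 0.8 * rnorm(n)
    plain_r <- function(x, y) {
      f <- summary(lm(y ~ x))
      t <- f$coefficients["x", "t value"]
      unname(sign(t) * sqrt(t^2 / (t^2 + n - 2)))
    }
    r_rob <- robust_partial_cor(edge, behavior)$r
    r_pl <- plain_r(edge, behavior)
    bad <- sample(n, 8)
    behavior[bad] <- behavior[bad] + 25
    c(
      rob = abs(robust_partial_cor(edge, behavior)$r - r_rob),
      plain = abs(plain_r(edge, behavior) - r_pl)
    )
  })
  expect_lt(mean(deltas["rob", ]), 0.5 * mean(deltas["plain", ]))
})

test_that("comparing correlations follows the Fisher z formula", {
  r <- compare_correlations(0.5, 30, 0.5, 40)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  r <- compare_correlations(-0.78, 16, 0.06, 62)
  expect_equal(abs(r$z), 3.61, tolerance = 0.005)
  a <- compare_correlations(0.7, 20, 0.2, 30)
  b <- compare_correlations(0.2, 30, 0.7, 20)
  expect_equal(a$z, -b$z)
  expect_error(compare_correlations(1, 10, 0.5, 10), "\\|r\\| < 1")
  expect_error(compare_correlations(0.5, 3, 0.5, 10), "n > 3")
})

test_that("subtype-specific coupling shows up only in the coupled group", {
  cohort <- generate_cohort(cohort_config(seed = 10))
  edges <- compute_edges(cohort)
  bb <- brain_behavior_cor(edges, cohort$subjects, "DMN-OTC",
    n_boot = 500, seed = 2
  )
  by_group <- bb$by_group
  expect_lt(by_group$r[by_group$group == "GeoPref ASD"], -0.35)
  expect_lt(abs(by_group$r[by_group$group == "nonGeo ASD"]), 0.3)
  expect_equal(by_group$n[by_group$group == "GeoPref ASD"], 16)
  expect_equal(by_group$n[by_group$group == "nonGeo ASD"], 62)
  expect_true(all(by_group$ci_low <= by_group$r & by_group$r <= by_group$ci_high))
  expect_s3_class(glance(bb), "tbl_df")
})
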