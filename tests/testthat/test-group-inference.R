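test_that("identical groups give F = 0 and separated groups tiny p", {
  ids <- sprintf("x%02d", 1:6)
  ed <- manual_edges(ids, c(1, 2, 3, 1, 2, 3))
  des <- manual_design(ids, rep(c("a", "b"), each = 3))
  fit <- fit_edge_glm(ed, des, "DMN-OTC", covariates = character(0))
  expect_equal(fit$statistic, 0)
  expect_equal(fit$partial_eta_sq, 0)

  set.seed(21)
  ids <- sprintf("y%02d", 1:8)
  v <- c(rep(0, 4), rep(1, 4)) + rnorm(8, 0, 1e-3)
  des <- manual_design(ids, rep(c("a", "b"), each = 4))
  fit <- fit_edge_glm(manual_edges(ids, v), des, "DMN-OTC", covariates = character(0))
  expect_lt(fit$p_value, 1e-3)
  # cross-check F against the stats::anova oracle
  oracle <- anova(lm(v ~ rep(c("a", "b"), each = 4)))
  expect_equal(fit$statistic, oracle$`F value`[1], tolerance = 1e-10)
})

test_that("case-control model on the full cohort has the study's df", {
  cohort <- generate_cohort(cohort_config(seed = 6))
  edges <- compute_edges(cohort)
  fit <- fit_edge_glm(edges, build_design(cohort$subjects, "case_control"), "DMN-PVC")
  expect_equal(fit$df, c(3, 189)) # 4 groups + age + sex + intercept on n = 195
  expect_gte(fit$partial_eta_sq, 0)
  expect_lte(fit$partial_eta_sq, 1)
  # partial eta squared recomputed from the two fits
  ss_g <- sum(residuals(fit$fit_reduced)^2) - fit$rss
  expect_equal(fit$partial_eta_sq, ss_g / (ss_g + fit$rss))
})

test_that("omnibus p-values are uniform under the null", {
  set.seed(22)
  n <- 40
  ids <- sprintf("n%02d", 1:n)
  des <- manual_design(ids, rep(c("a", "b"), each = n / 2),
    age = rnorm(n), sex = sample(c("M", "F"), n, replace = TRUE)
  )
  ps <- replicate(400, {
    fit <- fit_edge_glm(manual_edges(ids, rnorm(n)), des, "DMN-OTC")
    fit$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH control follows the step-up rule", {
  r <- fdr_bh(c(0.001, 0.02, 0.9), q = 0.05)
  expect_equal(r$discovered, c(TRUE, TRUE, FALSE))
  expect_equal(r$q_value, c(0.003, 0.03, 0.9))
  expect_false(any(fdr_bh(rep(1, 5))$discovered))
  expect_true(fdr_bh(0.04)$discovered) # m = 1 reduces to the raw threshold
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # fewer discoveries at stricter q
  set.seed(23)
  p <- runif(50)^2
  expect_lte(
    sum(fdr_bh(p, q = 0.01)$discovered),
    sum(fdr_bh(p, q = 0.05)$discovered)
  )
})

test_that("permutation test attains its minimum p on separated groups and is reproducible", {
  v <- c(rep(0, 10), rep(5, 10)) + rnorm(20, 0, 0.01)
  g <- rep(c("a", "b"), each = 10)
  r <- permutation_pairwise(v, g, n_perm = 200, seed = 1)
  expect_equal(r$perm_p, 1 / 201)
  r2 <- permutation_pairwise(v, g, n_perm = 200, seed = 1)
  expect_identical(r$perm_p, r2$perm_p)
  expect_gt(r$cohens_d, 5)
  expect_error(permutation_pairwise(v, g, n_perm = 50), "n_perm")
  expect_error(permutation_pairwise(v[1:11], c(rep("a", 10), "b"), n_perm = 100), "at least 2")
})

test_that("permutation p agrees with the parametric t-test without covariates", {
  set.seed(24)
  v <- c(rnorm(30), rnorm(30, 0.4))
  g <- rep(c("a", "b"), each = 30)
  r <- permutation_pairwise(v, g, n_perm = 4000, seed = 2)
  pt_p <- t.test(v ~ g, var.equal = TRUE)$p.value
  expect_lt(abs(r$perm_p - pt_p), 0.03)
})

test_that("Freedman-Lane permutation respects covariate structure", {
  # edge strongly driven by age; group effect null: p should not be inflated
  set.seed(25)
  rej <- mean(replicate(200, {
    age <- rnorm(40)
    v <- 2 * age + rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    permutation_pairwise(v, g, data.frame(age = age),
      n_perm = 200, seed = sample.int(1e6, 1)
    )$perm_p <= 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- rnorm(10)
  y <- rnorm(12, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("chi-square on the study's sex-by-group table reproduces the printed value", {
  tab <- rbind(
    c(27, 4), c(11, 5), c(49, 13), c(10, 5), c(8, 8), c(37, 18)
  )
  r <- contingency_chi2(tab)
  expect_equal(r$df, 5)
  expect_equal(r$statistic, 9.89, tolerance = 0.001)
  # independent hand computation of the Pearson statistic
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - e)^2 / e), tolerance = 1e-10)

  expect_equal(contingency_chi2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  prop <- rbind(c(10, 20), c(20, 40))
  expect_equal(contingency_chi2(prop)$statistic, 0)
  expect_error(contingency_chi2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("one-way ANOVA reduces to t-squared for two groups", {
  set.seed(26)
  v <- rnorm(30)
  g <- rep(c("a", "b"), each = 15)
  a <- oneway_anova(v, g)
  t2 <- t.test(v ~ g, var.equal = TRUE)$statistic^2
  expect_equal(a$statistic, unname(t2), tolerance = 1e-10)
  expect_error(oneway_anova(rep(1, 10), rep(c("a", "b"), 5)), "variance")
  expect_error(oneway_anova(rnorm(5), rep("a", 5)), "two groups")
})

test_that("a planted GeoPref deficit is detected on the right edge", {
  cohort <- generate_cohort(cohort_config(seed = 7))
  edges <- compute_edges(cohort)
  om <- edgewise_glm(edges, build_design(cohort$subjects, "subtype"))
  expect_true(om$discovered[om$edge == "DMN-OTC"])
  # pairwise follow-up finds GeoPref vs TD among the strongest contrasts
  pw <- pairwise_group_tests(edges, build_design(cohort$subjects, "subtype"),
    "DMN-OTC",
    n_perm = 500, seed = 1
  )
  gp_td <- pw[pw$group_a == "GeoPref ASD" & pw$group_b == "TD", ]
  expect_true(gp_td$discovered)
  expect_equal(nrow(pw), choose(5, 2))
  expect_true(all(pw$fdr_q >= pw$perm_p))
})
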