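test_that("default cohort reproduces the study's group structure", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  subj <- cohort$subjects
  expect_equal(nrow(subj), 195)
  counts <- table(subj$group)
  expect_equal(unname(counts[["GeoPref ASD"]]), 16)
  expect_equal(unname(counts[["nonGeo ASD"]]), 62)
  expect_equal(unname(counts[["ASD-noET"]]), 31)
  expect_equal(unname(counts[["TD"]]), 55)

  # subtype labels consistent with the 69 percent classifier
  expect_true(all(subj$pct_geo[subj$group == "GeoPref ASD"] >= 69))
  expect_true(all(subj$pct_geo[subj$group == "nonGeo ASD"] < 69))

  # missing-data pattern: eye tracking absent only for ASD-noET,
  # ADOS present only for ASD subjects
  expect_true(all(is.na(subj$pct_geo) == (subj$group == "ASD-noET")))
  asd <- subj$group %in% c("GeoPref ASD", "nonGeo ASD", "ASD-noET")
  expect_true(all(!is.na(subj$ados_sa[asd])))
  expect_true(all(is.na(subj$ados_sa[!asd])))
  expect_true(all(subj$ados_sa[asd] >= 0))
  expect_true(all(subj$mean_fd >= 0))

  # one time series and motion trace per subject, right shapes
  expect_named(cohort$timeseries, subj$subject_id)
  expect_equal(dim(cohort$timeseries[[1]]), c(150, 6))
  expect_equal(dim(cohort$motion[[1]]), c(150, 6))
  expect_false(anyNA(cohort$timeseries[[10]]))
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$motion, b$motion)
  c <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$subjects$age_scan_months, c$subjects$age_scan_months))
})

test_that("true_edge_values reads partial correlations off the precision matrix", {
  # no planted effects: identity precision, all edges zero
  cfg0 <- small_config(edge_effects = tibble::tibble(
    edge = character(), group = character(), partial_cor = double()
  ), behavior_coupling = tibble::tibble(
    edge = character(), group = character(), target_r = double(),
    behavior_mean = double(), behavior_sd = double()
  ))
  expect_true(all(true_edge_values(cfg0)$partial_cor == 0))

  # chain structure: DMN-OTC and OTC-PVC dependent, DMN-PVC conditionally
  # independent (off-diagonal -0.4 twice leaves the unplanted entry at 0)
  cfg_chain <- small_config(edge_effects = tibble::tibble(
    edge = c("DMN-OTC", "OTC-PVC"), group = "TD", partial_cor = 0.4
  ))
  tv <- true_edge_values(cfg_chain)
  td <- tv[tv$group == "TD", ]
  expect_equal(td$partial_cor[td$edge == "DMN-OTC"], 0.4)
  expect_equal(td$partial_cor[td$edge == "OTC-PVC"], 0.4)
  expect_equal(td$partial_cor[td$edge == "DMN-PVC"], 0)

  # round trip of a planted value
  cfg <- small_config()
  tv <- true_edge_values(cfg)
  expect_equal(
    tv$partial_cor[tv$group == "TD" & tv$edge == "DMN-OTC"], 0.30
  )
})

test_that("estimated edges are calibrated to the generating precision", {
  # rho -> 0, large T, no between-subject jitter: the mean estimated partial
  # correlation across replicate cohorts must sit within Monte-Carlo error of
  # the closed-form value implied by the precision matrix
  cfg_base <- list(
    group_sizes = c("TD" = 1), n_timepoints = 4000,
    component_labels = c("DMN", "OTC", "PVC", "DAN"),
    edge_sd = 0
  )
  ests <- vapply(1:100, function(i) {
    cfg <- do.call(cohort_config, c(cfg_base, list(seed = 1000 + i)))
    co <- generate_cohort(cfg)
    ed <- compute_edges(co, rho = 1e-10, fisher = FALSE)
    ed$value[ed$edge == "DMN-OTC"]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.30), 3 * mc_se + 0.002)
})

test_that("behavior coupling converges to the target correlation", {
  cfg <- cohort_config(group_sizes = c("GeoPref ASD" = 400), seed = 9)
  co <- generate_cohort(cfg)
  tr <- co$truth[co$truth$edge == "DMN-OTC", ]
  r <- cor(tr$true_partial_cor, co$subjects$ados_sa)
  expect_lt(abs(r - (-0.78)), 0.07)
})

test_that("inconsistent configurations are rejected", {
  expect_error(
    cohort_config(edge_effects = tibble::tibble(
      edge = "DMN-XXX", group = "TD", partial_cor = 0.3
    )),
    "does not name a pair"
  )
  expect_error(cohort_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(cohort_config(group_sizes = c("TD" = 0)), "positive")
  expect_error(
    cohort_config(edge_effects = tibble::tibble(
      edge = "DMN-OTC", group = "TD", partial_cor = 1.2
    )),
    "\\(-1, 1\\)"
  )
  expect_error(
    cohort_config(behavior_coupling = tibble::tibble(
      edge = "DMN-OTC", group = "Unknown", target_r = -0.5,
      behavior_mean = 10, behavior_sd = 3
    )),
    "unknown groups"
  )
})

test_that("AR(1) series have the intended temporal autocorrelation", {
  cfg <- cohort_config(
    group_sizes = c("TD" = 4), n_timepoints = 3000,
    ar_coefficient = 0.5, seed = 3
  )
  co <- generate_cohort(cfg)
  ac <- mean(vapply(co$timeseries, function(x) {
    mean(apply(x, 2, function(v) cor(v[-1], v[-length(v)])))
  }, numeric(1)))
  expect_lt(abs(ac - 0.5), 0.05)
})
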