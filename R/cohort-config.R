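#' Configure a synthetic toddler rsfMRI cohort
#'
#' Defines the statistical structure of a simulated cohort: group sizes
#' mirroring the study design (16 GeoPref ASD, 62 nonGeo ASD, 31 ASD without
#' eye tracking, 15 LD/DD, 16 TD ASDSib, 55 TD), per-group precision matrices
#' with planted partial-correlation edges, AR(1) temporal smoothing,
#' eye-tracking fixation distributions straddling the 69 percent cutoff,
#' subtype-specific coupling between a connectivity edge and ADOS social
#' affect, and head-motion levels matching the study's mean framewise
#' displacement per group.
#'
#' Planted edges are specified as target partial correlations; the generator
#' builds each group's precision matrix with unit diagonal and off-diagonal
#' `-target` at the named pairs, so the implied partial correlation equals the
#' target exactly (see [true_edge_values()]). Between-subject heterogeneity in
#' the true edge strengths is controlled by `edge_sd`.
#'
#' @param group_sizes Named integer vector of subjects per group. Names must
#'   come from [geo_groups()].
#' @param n_timepoints Number of fMRI volumes per subject (default 150).
#' @param repetition_time Sampling interval in seconds (default 2.5).
#' @param component_labels Names of the ICA components; the first four default
#'   to the analyzed networks DMN, OTC, PVC and DAN.
#' @param ar_coefficient AR(1) coefficient of the component time series, in
#'   `[0, 1)`.
#' @param edge_effects Data frame with columns `edge`, `group`,
#'   `partial_cor`: the target partial correlation of `edge` in `group`.
#'   Unlisted (edge, group) pairs have true partial correlation 0.
#' @param edge_sd Between-subject SD of the true partial correlation around
#'   the group target, applied to every edge named in `edge_effects` or
#'   `behavior_coupling`.
#' @param behavior_coupling Data frame with columns `edge`, `group`,
#'   `target_r`, `behavior_mean`, `behavior_sd`: in the named group, ADOS
#'   social affect is a linear function of the subject's true edge strength
#'   with Gaussian noise calibrated so the correlation equals `target_r`.
#' @param fixation_distributions Data frame with columns `group`, `mean`,
#'   `sd`: per-group percent-geometric-fixation distributions (truncated to
#'   `[0, 100]`; subtype membership is enforced around the 69 cutoff by
#'   rejection sampling).
#' @param age_range_months Length-2 numeric, age at scan range in months.
#' @param sex_male Named numeric vector, male fraction per group.
#' @param motion_level Named numeric vector, target mean framewise
#'   displacement (mm) per group.
#' @param motion_sdlog Lognormal SD (log scale) of the subject-to-subject
#'   spread around the group motion level; the default 0.83 gives a
#'   coefficient of variation near 1, matching the within-group FD dispersion
#'   typical of toddler cohorts, so small group differences in mean motion
#'   stay statistically unremarkable.
#' @param ados_mean,ados_sd Mean and SD of ADOS social affect totals in ASD
#'   groups without planted behavior coupling.
#' @param seed Integer seed consumed by [generate_cohort()].
#'
#' @return An object of class `cohort_config` (a list).
#' @seealso [generate_cohort()], [true_edge_values()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' sum(cfg$group_sizes) # 195 subjects, as in the study design
cohort_config <- function(group_sizes = c(
                            "GeoPref ASD" = 16, "nonGeo ASD" = 62,
                            "ASD-noET" = 31, "LD/DD" = 15,
                            "TD ASDSib" = 16, "TD" = 55
                          ),
                          n_timepoints = 150,
                          repetition_time = 2.5,
                          component_labels = c("DMN", "OTC", "PVC", "DAN", "IC05", "IC06"),
                          ar_coefficient = 0.3,
                          edge_effects = default_edge_effects(),
                          edge_sd = 0.12,
                          behavior_coupling = default_behavior_coupling(),
                          fixation_distributions = default_fixation_distributions(),
                          age_range_months = c(12, 48),
                          sex_male = c(
                            "GeoPref ASD" = 11 / 16, "nonGeo ASD" = 49 / 62,
                            "ASD-noET" = 27 / 31, "LD/DD" = 10 / 15,
                            "TD ASDSib" = 8 / 16, "TD" = 37 / 55
                          ),
                          motion_level = c(
                            "GeoPref ASD" = 0.06, "nonGeo ASD" = 0.09,
                            "ASD-noET" = 0.09, "LD/DD" = 0.10,
                            "TD ASDSib" = 0.08, "TD" = 0.10
                          ),
                          motion_sdlog = 0.83,
                          ados_mean = 14,
                          ados_sd = 4,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% geo_groups())) {
    abort("`group_sizes` must be named with labels from geo_groups()")
  }
  if (any(group_sizes <= 0) || any(group_sizes != round(group_sizes))) {
    abort("all group sizes must be positive whole numbers")
  }
  check_count(n_timepoints, "n_timepoints", lower = length(component_labels) + 2)
  check_number(repetition_time, "repetition_time", lower = 1e-6)
  check_number(ar_coefficient, "ar_coefficient", lower = 0, upper = 1 - 1e-9)
  check_number(edge_sd, "edge_sd", lower = 0)
  check_number(motion_sdlog, "motion_sdlog", lower = 0)
  if (anyDuplicated(component_labels)) abort("component labels must be unique")
  if (length(component_labels) < 4) abort("need at least 4 labeled components")
  check_count(seed, "seed", lower = -.Machine$integer.max)

  edge_effects <- as_tibble(edge_effects)
  behavior_coupling <- as_tibble(behavior_coupling)
  fixation_distributions <- as_tibble(fixation_distributions)

  cfg <- structure(
    list(
      group_sizes = group_sizes,
      n_timepoints = as.integer(n_timepoints),
      repetition_time = repetition_time,
      component_labels = component_labels,
      ar_coefficient = ar_coefficient,
      edge_effects = edge_effects,
      edge_sd = edge_sd,
      behavior_coupling = behavior_coupling,
      fixation_distributions = fixation_distributions,
      age_range_months = age_range_months,
      sex_male = sex_male,
      motion_level = motion_level,
      motion_sdlog = motion_sdlog,
      ados_mean = ados_mean,
      ados_sd = ados_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  groups <- names(cfg$group_sizes)
  for (tab in c("edge_effects", "behavior_coupling")) {
    d <- cfg[[tab]]
    if (nrow(d) == 0) next
    if (!all(c("edge", "group") %in% names(d))) {
      abort(sprintf("`%s` needs `edge` and `group` columns", tab))
    }
    # rows for known groups absent from this cohort are allowed and ignored
    bad <- setdiff(unique(d$group), geo_groups())
    if (length(bad)) {
      abort(sprintf("`%s` names unknown groups: %s", tab, paste(bad, collapse = ", ")))
    }
    for (e in unique(d$edge)) resolve_edge(e, cfg$component_labels)
  }
  if (nrow(cfg$edge_effects) &&
    any(abs(cfg$edge_effects$partial_cor) >= 1)) {
    abort("target partial correlations must lie in (-1, 1)")
  }
  if (nrow(cfg$behavior_coupling) &&
    any(abs(cfg$behavior_coupling$target_r) >= 1)) {
    abort("behavior coupling target correlations must lie in (-1, 1)")
  }
  fx <- cfg$fixation_distributions
  miss <- setdiff(setdiff(groups, "ASD-noET"), fx$group)
  if (length(miss)) {
    abort(paste0("fixation distribution missing for: ", paste(miss, collapse = ", ")))
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
default_edge_effects <- function() {
  tibble(
    edge = rep(c("DMN-OTC", "DMN-PVC", "DMN-DAN"), each = 6),
    group = rep(geo_groups(), times = 3),
    partial_cor = c(
      # DMN-OTC: marked GeoPref-specific deficit
      0.02, 0.17, 0.17, 0.28, 0.30, 0.30,
      # DMN-PVC: uniform ASD deficit
      0.14, 0.14, 0.14, 0.26, 0.28, 0.28,
      # DMN-DAN: uniform ASD deficit
      0.12, 0.12, 0.12, 0.20, 0.22, 0.22
    )
  )
}

#' @rdname cohort_config
#' @export
default_behavior_coupling <- function() {
  tibble(
    edge = "DMN-OTC", group = "GeoPref ASD",
    target_r = -0.78, behavior_mean = 14, behavior_sd = 4
  )
}

#' @rdname cohort_config
#' @export
default_fixation_distributions <- function() {
  tibble(
    group = c("GeoPref ASD", "nonGeo ASD", "LD/DD", "TD ASDSib", "TD"),
    mean = c(80, 40, 35, 30, 30),
    sd = c(8, 15, 13, 12, 12)
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", sum(x$group_sizes), "in", length(x$group_sizes), "groups\n")
  cat(
    "  time series:", x$n_timepoints, "volumes x",
    length(x$component_labels), "components (TR", x$repetition_time, "s, AR1",
    x$ar_coefficient, ")\n"
  )
  cat("  planted edges:", nrow(x$edge_effects), " behavior couplings:",
    nrow(x$behavior_coupling), "\n",
    sep = ""
  )
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Group-level generating precision matrix: unit diagonal, off-diagonal
# -target at planted pairs; symmetrized; positive definiteness enforced by
# shrinking all off-diagonals until the smallest eigenvalue clears 1e-6.
group_precision <- function(cfg, group) {
  k <- length(cfg$component_labels)
  theta <- diag(k)
  ee <- cfg$edge_effects[cfg$edge_effects$group == group, , drop = FALSE]
  if (nrow(ee)) {
    for (r in seq_len(nrow(ee))) {
      ij <- resolve_edge(ee$edge[r], cfg$component_labels)
      theta[ij$row, ij$col] <- theta[ij$col, ij$row] <- -ee$partial_cor[r]
    }
  }
  make_pd(theta)
}

make_pd <- function(theta, floor = 1e-6) {
  for (i in 1:200) {
    if (min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values) > floor) {
      return(theta)
    }
    off <- theta - diag(diag(theta))
    theta <- diag(diag(theta)) + 0.9 * off
  }
  abort("could not construct a positive-definite precision matrix")
}

#' Exact partial correlations implied by a cohort configuration
#'
#' Oracle for recovery tests: returns, for every component pair and group, the
#' partial correlation implied by that group's generating precision matrix
#' (`-theta_ij / sqrt(theta_ii * theta_jj)`, after any positive-definiteness
#' shrinkage).
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `group`, `edge`, `comp_i`, `comp_j`,
#'   `partial_cor`.
#' @export
#' @examples
#' truth <- true_edge_values(cohort_config())
#' truth[truth$edge == "DMN-OTC", ]
true_edge_values <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  idx <- edge_index(config$component_labels)
  purrr::map_dfr(names(config$group_sizes), function(g) {
    theta <- group_precision(config, g)
    d <- sqrt(diag(theta))
    pc <- -theta / outer(d, d)
    tibble(
      group = g, edge = idx$edge, comp_i = idx$comp_i, comp_j = idx$comp_j,
      partial_cor = pc[cbind(idx$row, idx$col)]
    )
  })
}
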