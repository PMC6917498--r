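#' Generate a synthetic cohort
#'
#' Simulates one full cohort under a [cohort_config()]: a subjects table, one
#' component time-series matrix per subject, and one motion-parameter trace
#' per subject. Component time series are drawn from a zero-mean stationary
#' AR(1) process whose stationary precision matrix equals the subject's
#' generating precision (innovation covariance `(1 - phi^2) * Sigma`), so the
#' partial correlations reported by [true_edge_values()] are exact. Subjects
#' classified GeoPref ASD always fixate at or above 69 percent geometric,
#' nonGeo ASD below; ASD subjects without eye tracking have missing `pct_geo`;
#' ADOS social affect is present only for ASD subjects and, in groups named in
#' the behavior coupling, is generated from the subject's true edge strength.
#'
#' @param config A [cohort_config()].
#' @return An object of class `geo_cohort`: a list with
#'   \describe{
#'     \item{subjects}{tibble, one row per subject (`subject_id`, `group`,
#'       `sex`, `age_scan_months`, `age_et_months`, `pct_geo`, `ados_sa`,
#'       `mean_fd`, `mean_dvars`).}
#'     \item{timeseries}{named list of `T x K` matrices, columns named by
#'       component.}
#'     \item{motion}{named list of `T x 6` matrices (3 translations in mm,
#'       3 rotations in radians).}
#'     \item{truth}{tibble of each subject's true partial correlation on the
#'       planted edges.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dplyr::count(cohort$subjects, group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  k <- length(config$component_labels)
  tt <- config$n_timepoints
  phi <- config$ar_coefficient
  jitter_edges <- unique(c(config$edge_effects$edge, config$behavior_coupling$edge))
  jit <- if (length(jitter_edges)) {
    ji <- purrr::map_dfr(jitter_edges, resolve_edge, labels = config$component_labels)
    list(row = ji$row, col = ji$col, edge = ji$edge)
  } else {
    list(row = integer(), col = integer(), edge = character())
  }

  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)
  ids <- sprintf("S%03d", seq_len(n_total))

  base_prec <- lapply(setNames(groups, groups), function(g) group_precision(config, g))
  base_pc <- true_edge_values(config)
  # group -> named vector of target partial correlations on the jittered edges
  base_targets <- lapply(setNames(groups, groups), function(g) {
    v <- base_pc[base_pc$group == g, ]
    setNames(v$partial_cor[match(jit$edge, v$edge)], jit$edge)
  })

  group_v <- sex_v <- character(n_total)
  age_scan <- age_et <- pct_geo <- ados <- mean_fd <- mean_dv <- rep(NA_real_, n_total)
  truth_mat <- matrix(NA_real_, n_total, length(jit$edge))
  timeseries <- setNames(vector("list", n_total), ids)
  motion <- setNames(vector("list", n_total), ids)

  s <- 0L
  for (g in groups) {
    n_g <- config$group_sizes[[g]]
    n_male <- round(config$sex_male[[g]] * n_g)
    sexes <- sample(c(rep("M", n_male), rep("F", n_g - n_male)))
    bc <- config$behavior_coupling[config$behavior_coupling$group == g, , drop = FALSE]
    if (nrow(bc)) {
      bc$edge <- vapply(
        bc$edge, function(e) resolve_edge(e, config$component_labels)$edge, ""
      )
    }
    for (i in seq_len(n_g)) {
      s <- s + 1L
      group_v[s] <- g
      sex_v[s] <- sexes[i]

      sp <- subject_precision(base_prec[[g]], base_targets[[g]], jit, config)
      timeseries[[s]] <- simulate_ar1_series(sp$theta, tt, phi, config$component_labels)
      # lognormal subject-to-subject spread in motion, mean = group level
      sdl <- config$motion_sdlog
      level <- config$motion_level[[g]] * exp(rnorm(1, -sdl^2 / 2, sdl))
      motion[[s]] <- simulate_motion(tt, level)
      if (length(jit$edge)) truth_mat[s, ] <- sp$true_edges

      age_scan[s] <- runif(1, config$age_range_months[1], config$age_range_months[2])
      has_et <- g != "ASD-noET"
      if (has_et) {
        age_et[s] <- max(6, age_scan[s] - abs(rnorm(1, 2, 1.5)))
        pct_geo[s] <- draw_pct_geo(g, config)
      }
      ados[s] <- draw_ados(g, sp$true_edges, base_targets[[g]], bc, config)

      mean_fd[s] <- framewise_displacement(motion[[s]])$mean_fd
      mean_dv[s] <- dvars(timeseries[[s]])$mean_dvars
    }
  }

  truth <- if (length(jit$edge)) {
    tibble(
      subject_id = rep(ids, each = length(jit$edge)),
      group = rep(group_v, each = length(jit$edge)),
      edge = rep(jit$edge, times = n_total),
      true_partial_cor = as.vector(t(truth_mat))
    )
  } else {
    tibble(
      subject_id = character(), group = character(),
      edge = character(), true_partial_cor = double()
    )
  }

  structure(
    list(
      subjects = tibble(
        subject_id = ids, group = group_v, sex = sex_v,
        age_scan_months = age_scan, age_et_months = age_et,
        pct_geo = pct_geo, ados_sa = ados,
        mean_fd = mean_fd, mean_dvars = mean_dv
      ),
      timeseries = timeseries,
      motion = motion,
      truth = truth,
      config = config
    ),
    class = "geo_cohort"
  )
}

#' @export
print.geo_cohort <- function(x, ...) {
  cat(
    "<geo_cohort>", nrow(x$subjects), "subjects,",
    length(x$config$component_labels), "components,",
    x$config$n_timepoints, "volumes\n"
  )
  print(dplyr::count(x$subjects, .data$group))
  invisible(x)
}

# Subject-level precision: group targets plus N(0, edge_sd) deviations on the
# planted edges (clamped to +/-0.9), re-shrunk toward the group matrix if the
# jitter breaks positive definiteness. Returns the realized true partial
# correlations on the jittered edges.
subject_precision <- function(theta_g, targets, jit, cfg) {
  theta <- theta_g
  if (length(jit$edge) && cfg$edge_sd > 0) {
    pc <- pmax(-0.9, pmin(0.9, targets + rnorm(length(targets), 0, cfg$edge_sd)))
    theta[cbind(jit$row, jit$col)] <- -pc
    theta[cbind(jit$col, jit$row)] <- -pc
    for (rep in 1:200) {
      ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-6) break
      theta <- theta_g + 0.9 * (theta - theta_g)
    }
  }
  true_edges <- if (length(jit$edge)) {
    d <- sqrt(diag(theta))
    v <- -theta[cbind(jit$row, jit$col)] / (d[jit$row] * d[jit$col])
    setNames(v, jit$edge)
  } else {
    setNames(numeric(0), character(0))
  }
  list(theta = theta, true_edges = true_edges)
}

# Stationary AR(1) with stationary covariance solve(theta), rescaled to unit
# stationary variance per component (partial correlations are invariant to
# component scale, so the precision-matrix oracle is untouched, while signal
# amplitude stays comparable across groups): innovations are
# N(0, (1 - phi^2) Sigma) and the initial state is a full-variance draw.
simulate_ar1_series <- function(theta, tt, phi, labels) {
  k <- ncol(theta)
  sigma <- stats::cov2cor(chol2inv(chol(theta)))
  r_chol <- chol(sigma)
  z0 <- drop(rnorm(k) %*% r_chol)
  innov <- matrix(rnorm(tt * k), tt, k) %*% r_chol * sqrt(1 - phi^2)
  x <- matrix(0, tt, k, dimnames = list(NULL, labels))
  prev <- z0
  for (t in seq_len(tt)) {
    prev <- phi * prev + innov[t, ]
    x[t, ] <- prev
  }
  x
}

# Random-walk motion trace whose expected mean FD (50 mm rotation radius)
# equals `level`: six i.i.d. Gaussian step streams, rotations scaled so their
# arc-length contribution matches the translations.
simulate_motion <- function(tt, level, radius = 50) {
  step_sd <- level / (6 * sqrt(2 / pi))
  steps <- cbind(
    matrix(rnorm(tt * 3, 0, step_sd), tt, 3),
    matrix(rnorm(tt * 3, 0, step_sd / radius), tt, 3)
  )
  steps[1, ] <- rnorm(6, 0, step_sd) # initial position, FD uses differences only
  trace <- apply(steps, 2, cumsum)
  colnames(trace) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  trace
}

# Percent geometric fixation: truncated normal per group, with subtype
# membership enforced by rejection sampling around the 69 cutoff.
draw_pct_geo <- function(group, cfg, cutoff = 69) {
  fx <- cfg$fixation_distributions
  row <- which(fx$group == group)
  if (!length(row)) return(NA_real_)
  m <- fx$mean[row[1]]
  s <- fx$sd[row[1]]
  ok <- function(x) {
    if (group == "GeoPref ASD") x >= cutoff else if (group == "nonGeo ASD") x < cutoff else TRUE
  }
  for (i in 1:1000) {
    x <- rnorm(1, m, s)
    if (x >= 0 && x <= 100 && ok(x)) return(x)
  }
  # numerically safe fallback for extreme configurations
  if (group == "GeoPref ASD") {
    cutoff + abs(rnorm(1, 0, 2))
  } else {
    max(0, min(cutoff - abs(rnorm(1, 0, 2)), 100))
  }
}

# ADOS social affect: ASD groups only; linear in the subject's true edge
# strength for coupled (edge, group) pairs, with noise SD set so the implied
# correlation with the true edge equals target_r.
draw_ados <- function(group, true_edges, targets, bc, cfg) {
  if (!group %in% asd_groups()) return(NA_real_)
  if (nrow(bc) == 0) {
    return(max(0, round(rnorm(1, cfg$ados_mean, cfg$ados_sd))))
  }
  bc <- bc[1, ]
  dev <- true_edges[[bc$edge]] - targets[[bc$edge]]
  slope <- bc$target_r * bc$behavior_sd / cfg$edge_sd
  noise_sd <- bc$behavior_sd * sqrt(1 - bc$target_r^2)
  max(0, round(bc$behavior_mean + slope * dev + rnorm(1, 0, noise_sd)))
}
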