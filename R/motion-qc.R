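#' Framewise displacement from motion parameters
#'
#' Per-transition head-motion summary: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of `rotation_radius` mm.
#' Depends only on parameter differences, so constant offsets have no effect.
#'
#' @param trace Numeric `T x 6` matrix: 3 translations (mm) then 3 rotations
#'   (radians unless `degrees = TRUE`).
#' @param rotation_radius Sphere radius for the rotation-to-displacement
#'   conversion, in mm (default 50).
#' @param degrees Are rotations stored in degrees? Converted on read.
#' @return List: `fd_series` (length `T - 1`, mm) and `mean_fd`.
#' @export
#' @examples
#' trace <- matrix(0, 20, 6)
#' trace[11:20, 1] <- 1 # a single 1 mm x-translation step
#' framewise_displacement(trace)$fd_series[10]
framewise_displacement <- function(trace, rotation_radius = 50, degrees = FALSE) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) abort("motion trace must have 6 columns (3 translations, 3 rotations)")
  if (nrow(trace) < 2) abort("need at least 2 frames")
  if (any(!is.finite(trace))) abort("non-finite motion parameters")
  check_number(rotation_radius, "rotation_radius", lower = 0)
  rot <- trace[, 4:6, drop = FALSE]
  if (degrees) rot <- rot * pi / 180
  d_trans <- abs(diff(trace[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot)) * rotation_radius
  fd <- rowSums(d_trans) + rowSums(d_rot)
  list(fd_series = unname(fd), mean_fd = mean(fd))
}

#' DVARS of a multivariate signal
#'
#' Root-mean-square, across signal dimensions, of the backward temporal
#' difference: `DVARS_t = sqrt(mean_m (x[t, m] - x[t - 1, m])^2)`. Applied
#' here to component time series (this pipeline carries no voxel data, where
#' the measure originates).
#'
#' @param signal Numeric `T x M` matrix.
#' @return List: `dvars_series` (length `T - 1`) and `mean_dvars`.
#' @export
dvars <- function(signal) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) abort("need at least 2 frames")
  if (any(!is.finite(signal))) abort("non-finite signal")
  dv <- sqrt(rowMeans(diff(signal)^2))
  list(dvars_series = unname(dv), mean_dvars = mean(dv))
}

#' Per-subject quality-control summaries for a cohort
#'
#' Computes mean framewise displacement from each subject's motion trace and
#' mean DVARS from each subject's component time series.
#'
#' @param cohort A `geo_cohort` (or a list with named `motion` and
#'   `timeseries` lists plus a `subjects` tibble).
#' @param rotation_radius Passed to [framewise_displacement()].
#' @return Tibble: `subject_id`, `group`, `mean_fd`, `mean_dvars`.
#' @export
qc_summaries <- function(cohort, rotation_radius = 50) {
  ids <- cohort$subjects$subject_id
  tibble(
    subject_id = ids,
    group = cohort$subjects$group,
    mean_fd = unname(purrr::map_dbl(
      cohort$motion[ids],
      ~ framewise_displacement(.x, rotation_radius)$mean_fd
    )),
    mean_dvars = unname(purrr::map_dbl(cohort$timeseries[ids], ~ dvars(.x)$mean_dvars))
  )
}

#' Group balance of head-motion QC metrics
#'
#' One-way ANOVA of mean framewise displacement and mean DVARS across groups,
#' mirroring the check that no group is asymmetrically affected by motion.
#'
#' @param summaries Tibble from [qc_summaries()] (or any tibble with `group`,
#'   `mean_fd`, `mean_dvars`).
#' @return Tibble with one row per metric: `metric`, `statistic`, `df1`,
#'   `df2`, `p_value`.
#' @export
qc_group_balance <- function(summaries) {
  purrr::map_dfr(c("mean_fd", "mean_dvars"), function(m) {
    dplyr::mutate(
      oneway_anova(summaries[[m]], summaries$group),
      metric = m, .before = 1
    )
  })
}
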