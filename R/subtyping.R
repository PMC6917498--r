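#' Classify ASD toddlers into GeoPref vs nonGeo subtypes
#'
#' Applies the eye-tracking cutoff: toddlers who spent at least `cutoff_pct`
#' percent of test time fixated on the dynamic geometric stimulus are labeled
#' "GeoPref ASD", the rest "nonGeo ASD". Missing fixation values (no usable
#' eye tracking) yield "unstratifiable".
#'
#' @param pct_geo Numeric vector of percent geometric fixation, in `[0, 100]`
#'   (`NA` allowed).
#' @param cutoff_pct Cutoff in percent (default 69).
#' @param inclusive Should a value exactly at the cutoff count as GeoPref
#'   (default `TRUE`, i.e. "69 percent or more")?
#' @return Character vector: "GeoPref ASD", "nonGeo ASD" or "unstratifiable".
#' @export
#' @examples
#' classify_geopref(c(69, 68.99, NA))
classify_geopref <- function(pct_geo, cutoff_pct = 69, inclusive = TRUE) {
  check_number(cutoff_pct, "cutoff_pct", lower = 1e-9, upper = 100 - 1e-9)
  if (any(!is.na(pct_geo) & (pct_geo < 0 | pct_geo > 100))) {
    abort("`pct_geo` must lie in [0, 100]")
  }
  geo <- if (inclusive) pct_geo >= cutoff_pct else pct_geo > cutoff_pct
  out <- ifelse(geo, "GeoPref ASD", "nonGeo ASD")
  out[is.na(pct_geo)] <- "unstratifiable"
  out
}

#' Build a design labeling for one modeling scheme
#'
#' Produces the per-subject group labeling (or continuous predictor) used by
#' the edge-wise GLMs, for one of three competing schemes:
#' \describe{
#'   \item{case_control}{all ASD subjects share one "ASD" label; TD, LD/DD and
#'     TD ASDSib are kept as separate groups rather than collapsed.}
#'   \item{subtype}{ASD is split into GeoPref / nonGeo by [classify_geopref()];
#'     ASD subjects without eye tracking are excluded (and listed).}
#'   \item{transdiagnostic}{the continuous percent geometric fixation is the
#'     predictor, with no group membership variable; subjects without eye
#'     tracking are excluded.}
#' }
#'
#' @param subjects Subjects tibble (as produced by [generate_cohort()] or
#'   [read_subjects()]).
#' @param scheme One of `"case_control"`, `"subtype"`, `"transdiagnostic"`.
#' @param cutoff_pct,inclusive Passed to [classify_geopref()].
#' @return An object of class `geo_design`: list with `scheme`, `data` (tibble
#'   `subject_id`, `label` or `pct_geo`, `age_scan_months`, `sex`) and
#'   `excluded` (tibble of dropped subjects with a reason).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' d <- build_design(cohort$subjects, "subtype")
#' nrow(d$data) # 164 = 195 - 31 ASD subjects without eye tracking
build_design <- function(subjects,
                         scheme = c("case_control", "subtype", "transdiagnostic"),
                         cutoff_pct = 69, inclusive = TRUE) {
  scheme <- match.arg(scheme)
  if (nrow(subjects) == 0) abort("`subjects` is empty")
  subjects <- as_tibble(subjects)

  keep <- rep(TRUE, nrow(subjects))
  if (scheme != "case_control") {
    keep <- !is.na(subjects$pct_geo)
  }
  excluded <- dplyr::transmute(subjects[!keep, , drop = FALSE],
    subject_id = .data$subject_id, group = .data$group,
    reason = "no eye tracking data"
  )

  kept <- subjects[keep, , drop = FALSE]
  data <- switch(scheme,
    case_control = dplyr::transmute(kept,
      subject_id = .data$subject_id,
      label = ifelse(.data$group %in% asd_groups(), "ASD", .data$group),
      age_scan_months = .data$age_scan_months, sex = .data$sex
    ),
    subtype = dplyr::transmute(kept,
      subject_id = .data$subject_id,
      label = ifelse(.data$group %in% asd_groups(),
        classify_geopref(.data$pct_geo, cutoff_pct, inclusive), .data$group
      ),
      age_scan_months = .data$age_scan_months, sex = .data$sex
    ),
    transdiagnostic = dplyr::transmute(kept,
      subject_id = .data$subject_id,
      pct_geo = .data$pct_geo,
      age_scan_months = .data$age_scan_months, sex = .data$sex
    )
  )

  if (scheme == "subtype" &&
    !any(data$label %in% c("GeoPref ASD", "nonGeo ASD"))) {
    abort("subtype scheme requires at least one eye-tracked ASD subject")
  }
  if (scheme != "transdiagnostic" && length(unique(data$label)) < 2) {
    abort("degenerate design: a categorical scheme needs at least two labels")
  }
  if (anyDuplicated(data$subject_id)) abort("duplicate subject ids in design")

  structure(list(scheme = scheme, data = data, excluded = excluded),
    class = "geo_design"
  )
}

#' @export
print.geo_design <- function(x, ...) {
  cat("<geo_design> scheme:", x$scheme, "-", nrow(x$data), "subjects retained,",
    nrow(x$excluded), "excluded\n")
  if (x$scheme != "transdiagnostic") print(dplyr::count(x$data, .data$label))
  invisible(x)
}
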