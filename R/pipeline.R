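subject_columns <- function() {
  c(
    "subject_id", "group", "sex", "age_scan_months", "age_et_months",
    "pct_geo", "ados_sa", "mean_fd", "mean_dvars"
  )
}

#' Read a subjects table
#'
#' Reads the per-subject CSV (columns `subject_id`, `group`, `sex`,
#' `age_scan_months`, `age_et_months`, `pct_geo`, `ados_sa`, `mean_fd`,
#' `mean_dvars`; missing values preserved). Unknown group labels and
#' out-of-range values are rejected; unknown extra columns are dropped with a
#' warning (lenient-read policy).
#'
#' @param path CSV file path.
#' @return Subjects tibble.
#' @export
read_subjects <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group")
  miss <- setdiff(required, names(df))
  if (length(miss)) abort(paste0("subjects file lacks columns: ", paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), subject_columns())
  if (length(extra)) {
    warn(paste0("ignoring unknown columns: ", paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  for (col in setdiff(subject_columns(), names(df))) df[[col]] <- NA_real_
  bad_group <- setdiff(unique(df$group), geo_groups())
  if (length(bad_group)) {
    abort(paste0("unknown group labels: ", paste(bad_group, collapse = ", ")))
  }
  if (any(!is.na(df$pct_geo) & (df$pct_geo < 0 | df$pct_geo > 100))) {
    abort("pct_geo outside [0, 100]")
  }
  if (any(!is.na(df$mean_fd) & df$mean_fd < 0)) abort("negative mean_fd")
  if (any(!is.na(df$ados_sa) & df$ados_sa < 0)) abort("negative ados_sa")
  df[, subject_columns()]
}

#' Write a generated cohort to disk
#'
#' Writes `subjects.csv`, one `timeseries/<id>.csv` per subject (header =
#' component labels), one `motion/<id>.csv` per subject, and a `config.json`
#' echo of the generating configuration.
#'
#' @param cohort A `geo_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "geo_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  for (id in names(cohort$timeseries)) {
    readr::write_csv(
      as_tibble(as.data.frame(cohort$timeseries[[id]])),
      file.path(dir, "timeseries", paste0(id, ".csv"))
    )
    readr::write_csv(
      as_tibble(as.data.frame(cohort$motion[[id]])),
      file.path(dir, "motion", paste0(id, ".csv"))
    )
  }
  cfg <- cohort$config
  jsonlite::write_json(
    cfg[setdiff(names(cfg), character(0))],
    file.path(dir, "config.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read per-subject matrices from a directory of CSVs
#'
#' @param dir Directory of `<subject_id>.csv` files.
#' @return Named list of numeric matrices.
#' @export
read_matrix_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) abort(paste0("no CSV files in ", dir))
  out <- lapply(files, function(f) {
    as.matrix(readr::read_csv(f, show_col_types = FALSE, progress = FALSE))
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one input source: either `cohort` (a [cohort_config()] to simulate)
#' or the three paths to an existing cohort on disk.
#'
#' @param cohort Optional [cohort_config()].
#' @param subjects_path,timeseries_dir,motion_dir Optional paths to an
#'   ingested cohort (as written by [write_cohort()]).
#' @param rho Ridge regularization for [compute_edges()].
#' @param cutoff_pct GeoPref cutoff passed to [build_design()].
#' @param focus_edges Edges carried into model comparison.
#' @param behavior_edge,behavior_groups Edge and groups for the
#'   brain-behavior stage.
#' @param n_perm Permutations per pairwise test.
#' @param k CV folds.
#' @param n_boot Bootstrap resamples for brain-behavior CIs.
#' @param power_n_experiments Simulated experiments in the power stage.
#' @param seed Global seed; each stage draws a deterministic substream.
#' @param out_dir Optional output directory; when given, every stage table is
#'   written as CSV alongside a `manifest.json`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, subjects_path = NULL,
                       timeseries_dir = NULL, motion_dir = NULL,
                       rho = 1, cutoff_pct = 69,
                       focus_edges = c("DMN-OTC", "DMN-PVC", "DMN-DAN"),
                       behavior_edge = "DMN-OTC",
                       behavior_groups = c("GeoPref ASD", "nonGeo ASD"),
                       n_perm = 1000, k = 5, n_boot = 2000,
                       power_n_experiments = 10000,
                       seed = 1, out_dir = NULL) {
  simulate <- !is.null(cohort)
  ingest <- !is.null(subjects_path)
  if (simulate == ingest) {
    abort("provide exactly one of `cohort` or `subjects_path` (+ directories)")
  }
  if (simulate) stopifnot(inherits(cohort, "cohort_config"))
  if (ingest && (is.null(timeseries_dir) || is.null(motion_dir))) {
    abort("ingestion needs `timeseries_dir` and `motion_dir`")
  }
  structure(
    list(
      cohort = cohort, subjects_path = subjects_path,
      timeseries_dir = timeseries_dir, motion_dir = motion_dir,
      rho = rho, cutoff_pct = cutoff_pct, focus_edges = focus_edges,
      behavior_edge = behavior_edge, behavior_groups = behavior_groups,
      n_perm = n_perm, k = k, n_boot = n_boot,
      power_n_experiments = power_n_experiments,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one cohort: simulate (or ingest) the data, motion
#' QC and demographic balance, subtype classification and design construction,
#' ridge partial-correlation edges, edge-wise omnibus GLMs with FDR plus
#' permutation pairwise follow-up on surviving edges, AIC / cross-validated
#' MAPE model comparison on the focus edges, the subtype-specific
#' brain-behavior correlation, and the unbalanced-design power analysis based
#' on the realized GeoPref and TD group sizes. Reruns with an identical
#' configuration reproduce every stochastic output bit-identically (each stage
#' consumes a substream derived from the global seed).
#'
#' @param config A [run_config()].
#' @return Named list of stage results (`subjects`, `qc`, `demographics`,
#'   `edges`, `omnibus`, `pairwise`, `model_comparison`, `brain_behavior`,
#'   `power`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("simulate/ingest", {
    if (!is.null(config$cohort)) {
      generate_cohort(config$cohort)
    } else {
      structure(
        list(
          subjects = read_subjects(config$subjects_path),
          timeseries = read_matrix_dir(config$timeseries_dir),
          motion = read_matrix_dir(config$motion_dir),
          truth = NULL,
          config = NULL
        ),
        class = "geo_cohort"
      )
    }
  })
  subjects <- cohort$subjects

  qc <- stage("qc", {
    s <- qc_summaries(cohort)
    list(summaries = s, balance = qc_group_balance(s))
  })
  demographics <- stage("qc", {
    tab <- table(subjects$group, subjects$sex)
    dplyr::bind_rows(
      dplyr::mutate(contingency_chi2(tab), test = "sex_by_group", .before = 1),
      dplyr::mutate(
        oneway_anova(subjects$age_scan_months, subjects$group),
        test = "age_by_group", .before = 1
      )
    )
  })

  designs <- stage("subtype", {
    lapply(
      setNames(
        c("case_control", "subtype", "transdiagnostic"),
        c("case_control", "subtype", "transdiagnostic")
      ),
      function(s) build_design(subjects, s, cutoff_pct = config$cutoff_pct)
    )
  })

  edges <- stage("connectivity", compute_edges(cohort, rho = config$rho))

  omnibus <- stage("group_diff", {
    purrr::map_dfr(c("case_control", "subtype"), function(s) {
      dplyr::mutate(edgewise_glm(edges, designs[[s]]), scheme = s, .before = 1)
    })
  })
  pairwise <- stage("group_diff", {
    surviving <- unique(omnibus$edge[omnibus$discovered & omnibus$scheme == "subtype"])
    if (!length(surviving)) {
      tibble()
    } else {
      purrr::map_dfr(surviving, function(e) {
        pairwise_group_tests(edges, designs$subtype, e,
          n_perm = config$n_perm, seed = stage_seed(config$seed, "group_diff")
        )
      })
    }
  })

  model_comparison <- stage("model_compare", {
    purrr::map(
      setNames(config$focus_edges, config$focus_edges),
      function(e) {
        compare_models(edges, subjects, e,
          k = config$k,
          seed = stage_seed(config$seed, "model_compare")
        )
      }
    )
  })

  brain_behavior <- stage("brain_behavior", {
    brain_behavior_cor(edges, subjects, config$behavior_edge,
      groups = config$behavior_groups, n_boot = config$n_boot,
      seed = stage_seed(config$seed, "brain_behavior")
    )
  })

  power <- stage("power", {
    n1 <- sum(subjects$group == "GeoPref ASD")
    n2 <- sum(subjects$group == "TD")
    d_min <- min_detectable_d(n1, n2)
    dplyr::bind_rows(
      tibble(
        d = d_min, n1 = n1, n2 = n2, alpha = 0.05,
        n_experiments = NA_integer_, power_hat = 0.80, se_hat = NA_real_,
        method = "analytic"
      ),
      empirical_power(d_min, n1, n2,
        n_experiments = config$power_n_experiments,
        seed = stage_seed(config$seed, "power")
      )
    )
  })

  manifest <- list(
    package = "geoconn",
    version = as.character(utils::packageVersion("geoconn")),
    seed = config$seed,
    stage_seeds = sapply(
      c("group_diff", "model_compare", "brain_behavior", "power"),
      function(s) stage_seed(config$seed, s)
    ),
    parameters = config[c(
      "rho", "cutoff_pct", "focus_edges", "behavior_edge", "behavior_groups",
      "n_perm", "k", "n_boot", "power_n_experiments"
    )],
    stages = c(
      "simulate/ingest", "qc", "subtype", "connectivity", "group_diff",
      "model_compare", "brain_behavior", "power"
    ),
    n_subjects = nrow(subjects)
  )

  out <- list(
    subjects = subjects, qc = qc, demographics = demographics,
    designs = designs, edges = edges, omnibus = omnibus, pairwise = pairwise,
    model_comparison = model_comparison, brain_behavior = brain_behavior,
    power = power, manifest = manifest, cohort = cohort
  )

  if (!is.null(config$out_dir)) stage("write", write_run(out, config$out_dir))
  out
}

write_run <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(out$qc$summaries, file.path(dir, "qc.csv"))
  readr::write_csv(out$qc$balance, file.path(dir, "qc_balance.csv"))
  readr::write_csv(out$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(out$edges, file.path(dir, "edges.csv"))
  readr::write_csv(out$omnibus, file.path(dir, "omnibus.csv"))
  if (nrow(out$pairwise)) readr::write_csv(out$pairwise, file.path(dir, "pairwise.csv"))
  readr::write_csv(
    purrr::map_dfr(out$model_comparison, tidy, .id = NULL),
    file.path(dir, "model_comparison.csv")
  )
  readr::write_csv(out$brain_behavior$by_group, file.path(dir, "brain_behavior.csv"))
  readr::write_csv(out$power, file.path(dir, "power.csv"))
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
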