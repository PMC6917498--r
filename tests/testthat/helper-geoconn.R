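# Shared fixtures, all built in code.

# A small, fast cohort configuration used where the full study-sized design
# is not needed.
small_config <- function(seed = 1, ...) {
  cohort_config(
    group_sizes = c(
      "GeoPref ASD" = 6, "nonGeo ASD" = 10, "ASD-noET" = 4,
      "LD/DD" = 4, "TD ASDSib" = 4, "TD" = 10
    ),
    n_timepoints = 60,
    component_labels = c("DMN", "OTC", "PVC", "DAN"),
    seed = seed,
    ...
  )
}

# Minimal design object for direct tests of the GLM machinery.
manual_design <- function(subject_id, label, age = 0, sex = "M",
                          scheme = "case_control") {
  structure(
    list(
      scheme = scheme,
      data = tibble::tibble(
        subject_id = subject_id, label = label,
        age_scan_months = rep_len(age, length(subject_id)),
        sex = rep_len(sex, length(subject_id))
      ),
      excluded = tibble::tibble()
    ),
    class = "geo_design"
  )
}

# Long edge tibble for a single named edge.
manual_edges <- function(subject_id, value, edge = "DMN-OTC") {
  parts <- strsplit(edge, "-", fixed = TRUE)[[1]]
  tibble::tibble(
    subject_id = subject_id, comp_i = parts[2], comp_j = parts[1],
    edge = edge, value = value
  )
}

# Sample T draws from a zero-mean MVN with the given precision matrix,
# independent of the package's own generator.
rmvn_precision <- function(tt, theta) {
  sigma <- solve(theta)
  matrix(rnorm(tt * ncol(theta)), tt) %*% chol(sigma)
}

# Closed-form partial correlations implied by a precision matrix.
pcor_from_precision <- function(theta) {
  d <- sqrt(diag(theta))
  r <- -theta / outer(d, d)
  diag(r) <- 0
  r
}
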