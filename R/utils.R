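# Internal helpers shared across modules.

#' Canonical group labels
#'
#' The six cohort groups used throughout: two eye-tracking-defined ASD
#' subtypes, ASD toddlers lacking eye tracking, and three non-ASD comparison
#' groups.
#'
#' @return Character vector of the six group labels.
#' @export
geo_groups <- function() {
  c("GeoPref ASD", "nonGeo ASD", "ASD-noET", "LD/DD", "TD ASDSib", "TD")
}

asd_groups <- function() c("GeoPref ASD", "nonGeo ASD", "ASD-noET")

# Deterministic per-stage seed substream derived from one global seed, so each
# pipeline stage reproduces independently of execution order.
stage_seed <- function(seed, stage) {
  stages <- c(
    "cohort", "qc", "subtype", "connectivity", "group_diff",
    "model_compare", "brain_behavior", "power"
  )
  i <- match(stage, stages)
  if (is.na(i)) abort(paste0("unknown pipeline stage: ", stage))
  (as.integer(seed) %% 1000003L) + 7919L * i
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream (the caller's state is restored on exit).
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be a whole number", name))
  invisible(as.integer(x))
}

# Canonical lower-triangle (column-major) edge order for a K x K matrix:
# (2,1), (3,1), ..., (K,1), (3,2), ... Edge names put the first-listed
# component first, e.g. components DMN (col 1) and OTC (col 2) -> "DMN-OTC".
edge_index <- function(labels) {
  k <- length(labels)
  if (k < 2) abort("need at least two components to define edges")
  j <- rep(seq_len(k - 1), times = (k - 1):1)
  i <- unlist(lapply(seq_len(k - 1), function(jj) seq(jj + 1, k)))
  tibble(
    row = i, col = j,
    comp_i = labels[i], comp_j = labels[j],
    edge = paste(labels[j], labels[i], sep = "-")
  )
}

# Resolve an edge name like "DMN-OTC" (either orientation) to matrix indices.
resolve_edge <- function(edge, labels) {
  idx <- edge_index(labels)
  hit <- idx$edge == edge |
    idx$edge == paste(rev(strsplit(edge, "-", fixed = TRUE)[[1]]), collapse = "-")
  if (!any(hit)) {
    abort(sprintf(
      "edge '%s' does not name a pair of labeled components (%s)",
      edge, paste(labels, collapse = ", ")
    ))
  }
  idx[which(hit)[1], , drop = FALSE]
}
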