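#' Analytic power of the two-sided independent-samples t-test
#'
#' Noncentral-t power: `P(|T| > t_crit)` with noncentrality
#' `delta = d * sqrt(n1 n2 / (n1 + n2))` and `df = n1 + n2 - 2`. Serves as the
#' closed-form oracle for [empirical_power()].
#'
#' @param d Standardized mean difference (Cohen's d), non-negative.
#' @param n1,n2 Group sizes (each at least 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' analytic_power(0.80751, 16, 55) # about 0.80
analytic_power <- function(d, n1, n2, alpha = 0.05) {
  check_number(d, "d", lower = 0)
  n1 <- check_count(n1, "n1", lower = 2)
  n2 <- check_count(n2, "n2", lower = 2)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Monte-Carlo power of the unbalanced two-sample design
#'
#' Each simulated experiment draws `n1` observations from `Normal(d, 1)` and
#' `n2` from `Normal(0, 1)` (i.i.d. draws from the infinite population) and
#' applies a two-sided pooled-variance t-test at level `alpha`; power is the
#' rejection proportion across experiments.
#'
#' @inheritParams analytic_power
#' @param n_experiments Number of simulated experiments (default 100000, the
#'   study's setting).
#' @param seed Integer seed.
#' @return Tibble of class `power_sim`: `d`, `n1`, `n2`, `alpha`,
#'   `n_experiments`, `power_hat`, `se_hat` (binomial SE), `method`.
#' @export
#' @examples
#' empirical_power(0.80751, 16, 55, n_experiments = 2000, seed = 1)
empirical_power <- function(d, n1, n2, alpha = 0.05, n_experiments = 100000,
                            seed = 1) {
  check_number(d, "d", lower = 0)
  n1 <- check_count(n1, "n1", lower = 2)
  n2 <- check_count(n2, "n2", lower = 2)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  n_experiments <- check_count(n_experiments, "n_experiments", lower = 1)
  df <- n1 + n2 - 2
  tc <- qt(1 - alpha / 2, df)
  reject <- with_local_seed(seed, {
    rej <- 0L
    batch <- 20000L
    done <- 0L
    while (done < n_experiments) {
      b <- min(batch, n_experiments - done)
      x <- matrix(rnorm(n1 * b, mean = d), n1, b)
      y <- matrix(rnorm(n2 * b), n2, b)
      mx <- colMeans(x)
      my <- colMeans(y)
      vx <- (colSums(x^2) - n1 * mx^2) / (n1 - 1)
      vy <- (colSums(y^2) - n2 * my^2) / (n2 - 1)
      sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / df
      tstat <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
      rej <- rej + sum(abs(tstat) > tc)
      done <- done + b
    }
    rej
  })
  p_hat <- reject / n_experiments
  structure(
    tibble(
      d = d, n1 = n1, n2 = n2, alpha = alpha,
      n_experiments = n_experiments, power_hat = p_hat,
      se_hat = sqrt(p_hat * (1 - p_hat) / n_experiments),
      method = "simulation"
    ),
    class = c("power_sim", "tbl_df", "tbl", "data.frame")
  )
}

#' Minimum detectable effect size at a target power
#'
#' Bisection on [analytic_power()] until `|power - target_power| < 1e-6`:
#' the smallest Cohen's d at which the two-sided independent-samples t-test
#' attains the target power for the given group sizes.
#'
#' @inheritParams analytic_power
#' @param target_power Target power in `(alpha, 1)`.
#' @return Cohen's d.
#' @export
#' @examples
#' min_detectable_d(16, 55) # about 0.807, the study's d = 0.80751
min_detectable_d <- function(n1, n2, alpha = 0.05, target_power = 0.80) {
  check_number(target_power, "target_power", lower = alpha + 1e-9, upper = 1 - 1e-12)
  lo <- 0
  hi <- 1
  while (analytic_power(hi, n1, n2, alpha) < target_power) {
    hi <- hi * 2
    if (hi > 100) abort("failed to bracket the target power")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pw <- analytic_power(mid, n1, n2, alpha)
    if (abs(pw - target_power) < 1e-6) return(mid)
    if (pw < target_power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
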