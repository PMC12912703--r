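#' Wilcoxon rank-sum test with normal approximation
#'
#' Two-sample rank-sum test as used by default in standard spatial
#' transcriptomics pipelines: all observations are pooled and mid-ranked, the
#' grade-A rank sum `W_X` is standardized by its null mean
#' `n_X (N + 1) / 2` and variance `n_X n_Y (N + 1) / 12`, and the two-sided
#' p-value is taken from the standard normal. Count data produce pervasive
#' ties, so the variance applies the standard tie correction by default
#' (disable with `tie_correction = FALSE` for the uncorrected textbook
#' formula).
#'
#' The test assumes independent observations; under spatial correlation its
#' type I error can be inflated or deflated (see the package vignette and
#' [run_type1_experiment()]).
#'
#' @param x_values,y_values Numeric expression values for grade A and grade B.
#' @param tie_correction Apply the mid-rank tie correction to the null
#'   variance (default `TRUE`).
#' @param continuity Apply a 0.5 continuity correction toward the null mean
#'   (default `FALSE`; spot counts per region are large in this setting).
#' @return One-row tibble, see [test_result()]. When every pooled value is
#'   identical the null variance is zero and the result carries
#'   `status = "degenerate_input"`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x_values, y_values, tie_correction = TRUE,
                              continuity = FALSE) {
  nx <- length(x_values)
  ny <- length(y_values)
  if (nx < 1 || ny < 1) abort("both samples must be non-empty.", class = "stgee_value_error")
  pooled <- c(x_values, y_values)
  n <- nx + ny
  r <- rank(pooled) # mid-ranks for ties
  wx <- sum(r[seq_len(nx)])
  mu_w <- nx * (n + 1) / 2
  sigma2_w <- nx * ny * (n + 1) / 12
  if (tie_correction) {
    ties <- table(pooled)
    sigma2_w <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  }
  if (sigma2_w <= 0) {
    return(test_result("wilcoxon", 0, 1, status = "degenerate_input"))
  }
  delta <- wx - mu_w
  if (continuity) delta <- sign(delta) * max(abs(delta) - 0.5, 0)
  z <- delta / sqrt(sigma2_w)
  test_result("wilcoxon", z, 2 * pnorm(-abs(z)))
}

#' Two-sample z-test (Welch form)
#'
#' Large-sample difference-of-means test: `z = (mean_X - mean_Y) /
#' sqrt(s2_X/n_X + s2_Y/n_Y)` with unpooled sample variances, referred to the
#' standard normal. Applicable to arbitrarily distributed data (including
#' counts) when each group has many spots, but assumes independent
#' observations.
#'
#' @param x_values,y_values Numeric expression values for grade A and grade B
#'   (each of length at least 2).
#' @return One-row tibble, see [test_result()]. Zero variance in both groups
#'   yields `status = "degenerate_input"` (p = 1 when the means also agree).
#' @examples
#' two_sample_z(rpois(100, 2), rpois(100, 3))
#' @export
two_sample_z <- function(x_values, y_values) {
  nx <- length(x_values)
  ny <- length(y_values)
  if (nx < 2 || ny < 2) abort("each sample needs at least 2 values.", class = "stgee_value_error")
  se2 <- var(x_values) / nx + var(y_values) / ny
  dm <- mean(x_values) - mean(y_values)
  if (se2 <= 0) {
    if (dm == 0) {
      return(test_result("ztest", 0, 1, status = "degenerate_input"))
    }
    return(test_result("ztest", sign(dm) * Inf, NA_real_, status = "degenerate_input"))
  }
  z <- dm / sqrt(se2)
  test_result("ztest", z, 2 * pnorm(-abs(z)))
}
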