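#' Null-simulation Type I error benchmark
#'
#' Repeatedly simulates a single gene under the null (`beta1 = 0`) from a
#' scenario and records, for each test, the fraction of two-sided p-values
#' below each significance level among converged replicates. Clustered GEE
#' methods (`"gee-wald"`, `"gee-gst"`) are run at every value of `m_values`,
#' with the spatial K-means partition computed once per `m` and reused across
#' replicates. Nonconvergent or degenerate replicates are excluded from the
#' denominator and reported in `failures` (set
#' `failures_as_nonrejection = TRUE` to count them as non-rejections
#' instead).
#'
#' @param scenario A [st_scenario()] with `beta1 = 0`.
#' @param methods Subset of [st_test_methods()].
#' @param m_values Working-cluster counts for the clustered GEE tests.
#' @param alphas Significance levels at which rejection rates are evaluated.
#' @param reps Number of replicate genes (10,000 gives a Monte-Carlo
#'   standard error of about 0.001 at alpha = 0.01).
#' @param seed Experiment seed; replicate streams are derived from it.
#' @param chunk_size Replicates simulated per block (memory knob only).
#' @param failures_as_nonrejection Count failed replicates as non-rejections.
#' @return A `type1_result` tibble: `method`, `m` (`NA` for non-clustered
#'   tests), `alpha`, `rate`, `mc_se` (`sqrt(rate (1 - rate) / reps)`),
#'   `reps` (converged), `failures`.
#' @examples
#' sc <- scenario_preset("independent", n_rows = 8, n_cols = 8)
#' run_type1_experiment(sc, methods = c("wilcoxon", "ztest"), reps = 50, seed = 1)
#' @export
run_type1_experiment <- function(scenario,
                                 methods = st_test_methods(),
                                 m_values = c(25, 100),
                                 alphas = c(0.01, 0.001, 0.0001),
                                 reps = 10000, seed = 1L, chunk_size = 1000L,
                                 failures_as_nonrejection = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$beta1 != 0) {
    abort("type I error experiments require a null scenario (beta1 = 0).",
      class = "stgee_value_error"
    )
  }
  out <- run_rejection_experiment(
    scenario, methods, m_values, alphas, reps, seed, chunk_size,
    failures_as_nonrejection
  )
  structure(out, class = c("type1_result", class(out)))
}

#' Power benchmark over a grade-effect grid
#'
#' Runs the rejection-rate machinery of [run_type1_experiment()] at each
#' value of a `beta1` grid (the grade-B log fold change), at a single
#' significance level. The `beta1 = 0` row, when present, is the type I
#' error rate by definition.
#'
#' @inheritParams run_type1_experiment
#' @param beta1_grid Grade-effect values to sweep (default
#'   `c(0, 0.25, 0.5, 0.75, 1, 1.5)`).
#' @param alpha Single significance level (default 0.001).
#' @param reps Replicates per grid point (default 1000).
#' @return A `power_result` tibble: `method`, `m`, `beta1`, `alpha`,
#'   `rate`, `mc_se`, `reps`, `failures`.
#' @examples
#' sc <- scenario_preset("independent", n_rows = 8, n_cols = 8)
#' run_power_experiment(sc,
#'   beta1_grid = c(0, 1), methods = "wilcoxon",
#'   alpha = 0.05, reps = 50, seed = 1
#' )
#' @export
run_power_experiment <- function(scenario,
                                 beta1_grid = c(0, 0.25, 0.5, 0.75, 1, 1.5),
                                 methods = setdiff(st_test_methods(), "ztest"),
                                 m_values = c(25, 100),
                                 alpha = 0.001, reps = 1000, seed = 1L,
                                 chunk_size = 1000L,
                                 failures_as_nonrejection = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"), length(alpha) == 1)
  rows <- purrr::map(seq_along(beta1_grid), function(k) {
    b1 <- beta1_grid[k]
    sc <- st_scenario(
      sigma2 = scenario$sigma2, kappa = scenario$kappa,
      beta0 = scenario$beta0, beta1 = b1, lattice = scenario$coords,
      grade_scheme = scenario$grade_scheme, seed = scenario$seed
    )
    # share the Cholesky factor: the covariance does not depend on beta1
    sc$cache$L <- scenario_chol(scenario)
    res <- run_rejection_experiment(
      sc, methods, m_values, alpha, reps,
      seed = derive_seed(seed, k, 7L), chunk_size, failures_as_nonrejection
    )
    dplyr::mutate(res, beta1 = b1, .after = "m")
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("power_result", class(out)))
}

# shared driver: simulate in chunks, test each replicate with every
# method/m combination, tally rejections per alpha
run_rejection_experiment <- function(scenario, methods, m_values, alphas,
                                     reps, seed, chunk_size,
                                     failures_as_nonrejection) {
  methods <- match.arg(methods, st_test_methods(), several.ok = TRUE)
  combos <- method_combos(methods, m_values)
  cl <- list()
  for (m in unique(stats::na.omit(combos$m))) {
    cl[[as.character(m)]] <- kmeans_spatial(scenario$coords, m = m, seed = seed)
  }
  rej <- matrix(0, nrow(combos), length(alphas))
  fail <- numeric(nrow(combos))
  done <- 0L
  while (done < reps) {
    take <- min(chunk_size, reps - done)
    Y <- simulate_gene_matrix(scenario, take, seed = seed, offset = done)
    for (k in seq_len(nrow(combos))) {
      g <- if (is.na(combos$m[k])) NULL else cl[[as.character(combos$m[k])]]
      res <- batch_test_matrix(Y, scenario$labels, combos$method[k], clusters = g)
      ok <- res$status == "ok"
      fail[k] <- fail[k] + sum(!ok)
      p <- res$p_value[ok]
      for (j in seq_along(alphas)) rej[k, j] <- rej[k, j] + sum(p < alphas[j])
    }
    done <- done + take
  }
  denom <- if (failures_as_nonrejection) rep(reps, nrow(combos)) else reps - fail
  rows <- purrr::map(seq_len(nrow(combos)), function(k) {
    rate <- as.numeric(rej[k, ]) / max(denom[k], 1)
    tibble(
      method = combos$method[k], m = combos$m[k], alpha = alphas,
      rate = rate, mc_se = sqrt(rate * (1 - rate) / max(denom[k], 1)),
      reps = as.integer(denom[k]), failures = as.integer(fail[k])
    )
  })
  dplyr::bind_rows(rows)
}

method_combos <- function(methods, m_values) {
  rows <- list()
  for (meth in methods) {
    if (meth %in% c("gee-wald", "gee-gst")) {
      for (m in m_values) rows[[length(rows) + 1]] <- tibble(method = meth, m = as.integer(m))
    } else {
      rows[[length(rows) + 1]] <- tibble(method = meth, m = NA_integer_)
    }
  }
  dplyr::bind_rows(rows)
}
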