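#' Tidy a Poisson estimating-equation fit
#'
#' Returns one row per coefficient in broom convention. Robust standard
#' errors require a working-cluster choice, so pass `clusters` (or leave
#' `NULL` for the one-spot-per-cluster HC0 form used by the Independent
#' GEE); without a converged fit the error columns are `NA`.
#'
#' @param x A [fit_poisson_ee()] object.
#' @param clusters Passed to [sandwich_covariance()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @examples
#' tidy(fit_poisson_ee(rpois(40, 2), rep(0:1, 20)))
#' @export
tidy.gee_fit <- function(x, clusters = NULL, ...) {
  out <- tibble(
    term = c("(Intercept)", "gradeB"),
    estimate = unname(x$beta),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
  if (x$converged) {
    v <- tryCatch(sandwich_covariance(x, clusters), error = function(e) NULL)
    if (!is.null(v)) {
      se <- sqrt(pmax(diag(v), 0))
      out$std.error <- se
      out$statistic <- ifelse(se > 0, out$estimate / se, NA_real_)
      out$p.value <- 2 * pnorm(-abs(out$statistic))
    }
  }
  if (x$restrict_null) out <- out[1, ]
  out
}

#' Glance at a Poisson estimating-equation fit
#'
#' @param x A [fit_poisson_ee()] object.
#' @param ... Unused.
#' @return One-row tibble with `nobs`, `converged`, `n_iter`, `status`.
#' @export
glance.gee_fit <- function(x, ...) {
  tibble(
    nobs = length(x$y), converged = x$converged,
    n_iter = x$n_iter, status = x$status
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
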