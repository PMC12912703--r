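test_that("two-group Poisson fit recovers the closed-form group-mean MLE", {
  fit <- fit_poisson_ee(c(1, 3, 2, 6), c(0, 0, 1, 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), c(log(2), log(2)), tolerance = 1e-10)
  expect_equal(fit$mu, c(2, 2, 4, 4), tolerance = 1e-10)

  set.seed(17)
  for (rep in 1:10) {
    y <- rpois(40, exp(runif(1, -1, 1)))
    x <- rep(0:1, 20)
    if (sum(y[x == 0]) == 0 || sum(y[x == 1]) == 0) next
    fit <- fit_poisson_ee(y, x)
    expect_equal(unname(fit$beta),
      c(log(mean(y[x == 0])), log(mean(y[x == 1]) / mean(y[x == 0]))),
      tolerance = 1e-10
    )
    # independent oracle: iterative solve by a different code path
    ref <- stats::glm(y ~ x, family = stats::poisson)
    expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-6)
  }
})

test_that("null-restricted fit is the intercept-only Poisson MLE", {
  y <- c(0, 1, 2, 3)
  fit <- fit_poisson_ee(y, c(0, 0, 1, 1), restrict_null = TRUE)
  expect_equal(unname(fit$beta), c(log(1.5), 0), tolerance = 1e-10)
})

test_that("degenerate and separated inputs are flagged, not fitted", {
  z <- fit_poisson_ee(rep(0, 8), rep(0:1, 4))
  expect_equal(z$status, "degenerate_input")
  sep <- fit_poisson_ee(c(2, 3, 0, 0), c(0, 0, 1, 1))
  expect_equal(sep$status, "nonconvergence")
  expect_false(sep$converged)
  # GST still returns a finite statistic under separation
  gst <- generalized_score_test(c(2, 3, 0, 0), c(0, 0, 1, 1))
  expect_equal(gst$status, "ok")
  expect_true(is.finite(gst$statistic))
  # ... while the Wald test does not
  wald <- robust_wald_test(c(2, 3, 0, 0), c(0, 0, 1, 1))
  expect_equal(wald$status, "nonconvergence")
  expect_true(is.na(wald$p_value))
})

test_that("sandwich equals the HC0 and clustered oracles from the sandwich package", {
  set.seed(2)
  y <- rpois(120, 2)
  x <- rep(0:1, 60)
  g <- rep(1:12, each = 10)
  fit <- fit_poisson_ee(y, x)
  ref <- stats::glm(y ~ x, family = stats::poisson)

  v_hc0 <- sandwich_covariance(fit, clusters = NULL)
  expect_equal(max(abs(v_hc0 - sandwich::vcovHC(ref, type = "HC0"))), 0,
    tolerance = 1e-10
  )
  v_cl <- sandwich_covariance(fit, clusters = g)
  expect_equal(
    max(abs(v_cl - sandwich::vcovCL(ref, cluster = g, type = "HC0", cadjust = FALSE))),
    0,
    tolerance = 1e-10
  )
})

test_that("clustered sandwich equals an explicit per-cluster summation oracle", {
  set.seed(3)
  y <- rpois(60, 1.2)
  x <- rep(c(0, 1), 30)
  g <- sample(rep(1:6, each = 10))
  fit <- fit_poisson_ee(y, x)
  mu <- fit$mu
  bread <- matrix(0, 2, 2)
  meat <- matrix(0, 2, 2)
  for (c in unique(g)) {
    idx <- which(g == c)
    D <- cbind(mu[idx], mu[idx] * x[idx]) # d mu / d beta
    Vi <- diag(mu[idx], nrow = length(idx))
    s <- t(D) %*% solve(Vi) %*% (y[idx] - mu[idx])
    bread <- bread + t(D) %*% solve(Vi) %*% D
    meat <- meat + s %*% t(s)
  }
  oracle <- solve(bread) %*% meat %*% solve(bread)
  v <- sandwich_covariance(fit, clusters = g)
  expect_equal(max(abs(v - oracle)), 0, tolerance = 1e-10)
  expect_equal(max(abs(attr(v, "bread") - bread)), 0, tolerance = 1e-8)
  expect_equal(max(abs(attr(v, "meat") - meat)), 0, tolerance = 1e-8)
})

test_that("duplicating every cluster doubles bread and meat, halving the covariance", {
  set.seed(4)
  y <- rpois(40, 2)
  x <- rep(0:1, 20)
  g <- rep(1:4, each = 10)
  v1 <- sandwich_covariance(fit_poisson_ee(y, x), g)
  v2 <- sandwich_covariance(fit_poisson_ee(c(y, y), c(x, x)), c(g, g + 4))
  expect_equal(v2, v1 / 2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("perfect fit gives zero meat and zero covariance", {
  y <- c(2, 2, 4, 4) # group means fit exactly
  v <- sandwich_covariance(fit_poisson_ee(y, c(0, 0, 1, 1)), c(1, 1, 2, 2))
  expect_equal(unclass(v), matrix(0, 2, 2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Wald statistic composes estimate and oracle covariance; equal means give p = 1", {
  set.seed(6)
  y <- rpois(80, 1.5)
  x <- rep(0:1, 40)
  g <- rep(1:8, each = 10)
  fit <- fit_poisson_ee(y, x)
  ref <- stats::glm(y ~ x, family = stats::poisson)
  w_oracle <- stats::coef(ref)[["x"]] /
    sqrt(sandwich::vcovCL(ref, cluster = g, type = "HC0", cadjust = FALSE)[2, 2])
  res <- robust_wald_test(y, x, g)
  expect_equal(res$statistic, w_oracle, tolerance = 1e-8)
  expect_equal(res$p_value, 2 * pnorm(-abs(w_oracle)), tolerance = 1e-8)

  y_eq <- c(1, 3, 3, 1) # equal group means
  res_eq <- robust_wald_test(y_eq, c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(res_eq$statistic, 0)
  expect_equal(res_eq$p_value, 1)
})

test_that("GST matches an explicit dense m-term summation oracle", {
  set.seed(8)
  y <- rpois(60, 0.8)
  x <- rep(0:1, 30)
  g <- sample(rep(1:6, each = 10))
  ybar <- mean(y)
  nb_frac <- mean(x)
  e <- u1 <- numeric(6)
  for (c in 1:6) {
    idx <- which(g == c)
    r <- y[idx] - ybar
    u0c <- sum(r)
    u1[c] <- sum(r * x[idx])
    # bread blocks at the null fit: B10 B00^-1 = (nB ybar)/(n ybar) = nB/n
    e[c] <- u1[c] - nb_frac * u0c
  }
  s_oracle <- sum(u1) / sqrt(sum(e^2))
  res <- generalized_score_test(y, x, g)
  expect_equal(res$statistic, s_oracle, tolerance = 1e-10)

  # score vanishes at equal group means
  res_eq <- generalized_score_test(c(1, 3, 3, 1), c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(res_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(res_eq$p_value, 1, tolerance = 1e-12)
  # all-zero gene is degenerate
  expect_equal(
    generalized_score_test(rep(0, 8), rep(0:1, 4))$status,
    "degenerate_input"
  )
})

test_that("point estimates are invariant to the working partition; only the sandwich changes", {
  set.seed(10)
  y <- rpois(60, 2)
  x <- rep(0:1, 30)
  f <- fit_poisson_ee(y, x)
  # the estimating equations do not involve the partition at all under
  # working independence; assert the documented consequence on the tests
  p1 <- robust_wald_test(y, x, rep(1:3, each = 20))
  p2 <- robust_wald_test(y, x, rep(1:6, each = 10))
  b1 <- log(mean(y[x == 1]) / mean(y[x == 0]))
  expect_equal(p1$statistic * sqrt(sandwich_covariance(f, rep(1:3, each = 20))[2, 2]), b1,
    tolerance = 1e-10
  )
  expect_equal(p2$statistic * sqrt(sandwich_covariance(f, rep(1:6, each = 10))[2, 2]), b1,
    tolerance = 1e-10
  )
})

test_that("GST is invariant to cluster relabeling and ordering", {
  set.seed(11)
  y <- rpois(50, 1)
  x <- rbinom(50, 1, 0.5)
  x[1:2] <- c(0, 1)
  g <- sample(rep(1:5, each = 10))
  a <- generalized_score_test(y, x, g)
  perm <- sample(5)
  b <- generalized_score_test(y, x, perm[g])
  expect_identical(a$p_value, b$p_value)
})

test_that("robust covariance is symmetric PSD across random fits", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 40
    y <- rpois(n, exp(rnorm(1)))
    x <- rep(0:1, n / 2)
    if (sum(y[x == 0]) == 0 || sum(y[x == 1]) == 0) next
    g <- sample(1:8, n, replace = TRUE)
    v <- sandwich_covariance(fit_poisson_ee(y, x), g)
    expect_equal(v[1, 2], v[2, 1])
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-12))
  }
})

test_that("independent GEE equals the m = n robust Wald test", {
  set.seed(14)
  y <- rpois(30, 2)
  x <- rep(0:1, 15)
  a <- independent_gee_test(y, x)
  b <- robust_wald_test(y, x, seq_along(y))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("tidy and glance report coefficients and fit metadata", {
  set.seed(15)
  y <- rpois(40, 2)
  x <- rep(0:1, 20)
  fit <- fit_poisson_ee(y, x)
  td <- tidy(fit, clusters = rep(1:4, each = 10))
  expect_equal(td$term, c("(Intercept)", "gradeB"))
  expect_equal(td$estimate, unname(fit$beta))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 40L)
  expect_true(gl$converged)
})
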