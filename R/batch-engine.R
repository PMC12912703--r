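# Vectorized per-replicate test engine.
#
# The five tests reduce to group/cluster sums for a binary covariate, so a
# whole block of replicate genes (columns of Y) can be tested with matrix
# arithmetic. Closed forms used here:
#   * two-group Poisson EE fit: beta0 = log(meanA), beta1 = log(meanB/meanA);
#     bread = [[sumA+sumB, sumB], [sumB, sumB]] (= sum of fitted means);
#   * clustered sandwich: per-cluster score s_c = (sum_c r_i, sum_{c,B} r_i)
#     with r = y - mu, meat = sum_c s_c s_c';
#   * GST at the null fit (mu = ybar): per-cluster (U0c, U1c), nuisance
#     adjustment e_c = U1c - (nB/n) U0c, Var = sum e_c^2, S = sum U1c / se.
# Equality with the scalar implementations (fit_poisson_ee etc.) is asserted
# in the test suite; the scalar path is the reference.

batch_test_matrix <- function(Y, x, method, clusters = NULL) {
  n <- nrow(Y)
  a <- which(x == 0)
  b <- which(x == 1)
  dimnames(Y) <- NULL
  switch(method,
    "wilcoxon" = batch_wilcoxon(Y, a, b),
    "ztest" = batch_ztest(Y, a, b),
    "independent-gee" = batch_gee_wald(Y, a, b, g = seq_len(n), tag = "independent-gee"),
    "gee-wald" = batch_gee_wald(Y, a, b, g = cluster_ids(clusters, n), tag = "gee-wald"),
    "gee-gst" = batch_gee_gst(Y, a, b, g = cluster_ids(clusters, n)),
    abort(sprintf("unknown method tag '%s'.", method), class = "stgee_value_error")
  )
}

batch_gee_wald <- function(Y, a, b, g, tag) {
  na <- length(a)
  nb <- length(b)
  sum_a <- colSums(Y[a, , drop = FALSE])
  sum_b <- colSums(Y[b, , drop = FALSE])
  tot <- sum_a + sum_b
  beta1 <- log((sum_b / nb) / (sum_a / na))
  mu <- matrix(0, nrow(Y), ncol(Y))
  mu[a, ] <- rep(sum_a / na, each = na)
  mu[b, ] <- rep(sum_b / nb, each = nb)
  r <- Y - mu
  rb <- r
  rb[a, ] <- 0
  s0 <- rowsum(r, g)
  s1 <- rowsum(rb, g)
  m11 <- colSums(s0 * s0)
  m12 <- colSums(s0 * s1)
  m22 <- colSums(s1 * s1)
  # var(beta1) = row2(B^-1) M row2(B^-1)' with B = [[tot, sum_b],[sum_b, sum_b]]
  det <- sum_a * sum_b
  v <- (sum_b^2 * m11 - 2 * sum_b * tot * m12 + tot^2 * m22) / det^2
  stat <- ifelse(v > 0, beta1 / sqrt(v), ifelse(beta1 == 0, 0, NA_real_))
  p <- ifelse(is.na(stat), NA_real_, 2 * pnorm(-abs(stat)))
  p[!is.na(stat) & stat == 0 & v <= 0] <- 1
  status <- rep("ok", ncol(Y))
  status[is.na(p)] <- "nonconvergence"
  sep <- sum_a == 0 | sum_b == 0
  stat[sep] <- NA_real_
  p[sep] <- NA_real_
  status[sep] <- "nonconvergence"
  status[tot == 0] <- "degenerate_input"
  list(statistic = stat, p_value = p, status = status, method = tag)
}

batch_gee_gst <- function(Y, a, b, g) {
  n <- nrow(Y)
  nb <- length(b)
  tot <- colSums(Y)
  ybar <- tot / n
  r <- Y - rep(ybar, each = n)
  rb <- r
  rb[a, ] <- 0
  u0 <- rowsum(r, g)
  u1 <- rowsum(rb, g)
  e <- u1 - (nb / n) * u0
  score <- colSums(u1)
  v <- colSums(e * e)
  stat <- ifelse(v > 0, score / sqrt(v), ifelse(abs(score) < 1e-12, 0, NA_real_))
  p <- ifelse(is.na(stat), NA_real_, 2 * pnorm(-abs(stat)))
  p[!is.na(stat) & v <= 0 & abs(score) < 1e-12] <- 1
  status <- rep("ok", ncol(Y))
  status[is.na(p)] <- "nonconvergence"
  status[tot == 0] <- "degenerate_input"
  p[tot == 0] <- NA_real_
  stat[tot == 0] <- NA_real_
  list(statistic = stat, p_value = p, status = status, method = "gee-gst")
}

batch_ztest <- function(Y, a, b) {
  na <- length(a)
  nb <- length(b)
  sum_a <- colSums(Y[a, , drop = FALSE])
  sum_b <- colSums(Y[b, , drop = FALSE])
  mean_a <- sum_a / na
  mean_b <- sum_b / nb
  va <- (colSums(Y[a, , drop = FALSE]^2) - na * mean_a^2) / (na - 1)
  vb <- (colSums(Y[b, , drop = FALSE]^2) - nb * mean_b^2) / (nb - 1)
  se2 <- va / na + vb / nb
  dm <- mean_a - mean_b
  stat <- ifelse(se2 > 0, dm / sqrt(se2), ifelse(dm == 0, 0, NA_real_))
  p <- ifelse(is.na(stat), NA_real_, 2 * pnorm(-abs(stat)))
  p[se2 <= 0 & dm == 0] <- 1
  status <- rep("ok", ncol(Y))
  status[se2 <= 0] <- "degenerate_input"
  p[se2 <= 0 & dm != 0] <- NA_real_
  list(statistic = stat, p_value = p, status = status, method = "ztest")
}

batch_wilcoxon <- function(Y, a, b) {
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  R <- ncol(Y)
  stat <- numeric(R)
  p <- numeric(R)
  status <- rep("ok", R)
  mu_w <- na * (n + 1) / 2
  for (j in seq_len(R)) {
    y <- Y[, j]
    rk <- rank(y)
    wx <- sum(rk[a])
    t <- rle(sort.int(y, method = "radix"))$lengths
    sigma2 <- na * nb / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    if (sigma2 <= 0) {
      stat[j] <- 0
      p[j] <- 1
      status[j] <- "degenerate_input"
    } else {
      z <- (wx - mu_w) / sqrt(sigma2)
      stat[j] <- z
      p[j] <- 2 * pnorm(-abs(z))
    }
  }
  list(statistic = stat, p_value = p, status = status, method = "wilcoxon")
}
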