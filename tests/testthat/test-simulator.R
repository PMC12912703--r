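test_that("hex lattice has unit nearest-neighbour spacing", {
  two <- generate_visium_lattice(1, 2)
  expect_equal(nrow(two), 2)
  expect_equal(euclidean_distance_matrix(two)[1, 2], 1)

  sq <- generate_visium_lattice(2, 2)
  d <- euclidean_distance_matrix(sq)
  nn <- apply(d + diag(Inf, 4), 1, min)
  expect_equal(nn, rep(1, 4), tolerance = 1e-12)

  big <- generate_visium_lattice(59, 59)
  expect_equal(nrow(big), 3481)
})

test_that("exponential covariance follows sigma2 * exp(-tau/kappa)", {
  coords <- cbind(x = c(0, 2, 5), y = 0)
  v <- build_spatial_covariance(coords, sigma2 = 1.5, kappa = 2)
  expect_equal(diag(v), rep(1.5, 3)) # tau = 0
  expect_equal(v[1, 2], 1.5 * exp(-1)) # tau = kappa
  expect_equal(v[1, 3], 1.5 * exp(-5 / 2))
  expect_equal(build_spatial_covariance(coords, 0, 1), matrix(0, 3, 3))
  expect_error(build_spatial_covariance(coords, 1, 0), class = "stgee_value_error")
})

test_that("grade assignment is balanced under both schemes", {
  line <- cbind(x = 1:4, y = 0)
  expect_equal(assign_grades(line), c(0L, 0L, 1L, 1L))
  for (n_rows in c(5, 8)) {
    coords <- generate_visium_lattice(n_rows, 7)
    for (scheme in c("spatial-half-split", "random-balanced")) {
      lab <- assign_grades(coords, scheme, seed = 4)
      expect_lte(abs(sum(lab == 0) - sum(lab == 1)), 1)
    }
  }
})

test_that("simulation is reproducible and chunk-invariant", {
  sc <- st_scenario(1, 2, lattice = generate_visium_lattice(6, 6), seed = 77)
  expect_identical(simulate_gene(sc), simulate_gene(sc))
  all_at_once <- simulate_genes(sc, 6, seed = 3)
  in_chunks <- cbind(
    simulate_genes(sc, 2, seed = 3, offset = 0),
    simulate_genes(sc, 4, seed = 3, offset = 2)
  )
  expect_identical(all_at_once, in_chunks)
  # single-gene path equals the first column of the batched path
  expect_identical(simulate_gene(sc, seed = 3), simulate_genes(sc, 1, seed = 3)[, 1])
})

test_that("independence limit gives iid Poisson(exp(beta0)) counts", {
  sc <- st_scenario(0, 1,
    beta0 = -1, lattice = generate_visium_lattice(6, 6),
    seed = 5
  )
  Y <- simulate_genes(sc, 3000, seed = 5)
  expect_equal(mean(Y), exp(-1), tolerance = 3 * sqrt(exp(-1) / length(Y)))
})

test_that("marginal moments match the Poisson log-normal closed forms", {
  # E[Y] = exp(beta0 + beta1 X + sigma2/2); Var = mean + (e^sigma2 - 1) mean^2
  sigma2 <- 1
  beta0 <- -1.5
  beta1 <- 0.6
  sc <- st_scenario(sigma2, 2,
    beta0 = beta0, beta1 = beta1,
    lattice = generate_visium_lattice(6, 6), seed = 6
  )
  reps <- 50000
  Y <- simulate_genes(sc, reps, seed = 8)
  for (grade in 0:1) {
    spot <- which(sc$labels == grade)[1]
    m_true <- exp(beta0 + beta1 * grade + sigma2 / 2)
    v_true <- m_true + (exp(sigma2) - 1) * m_true^2
    draws <- Y[spot, ]
    expect_lt(abs(mean(draws) - m_true), 3 * sqrt(v_true / reps))
    # variance check with generous MC slack (4th-moment heavy tails)
    expect_lt(abs(var(draws) - v_true), 0.15 * v_true)
  }
})

test_that("latent field covariance matches sigma2 * exp(-tau/kappa) empirically", {
  sigma2 <- 0.8
  kappa <- 2
  lattice <- generate_visium_lattice(5, 5)
  sc <- st_scenario(sigma2, kappa, lattice = lattice, seed = 9)
  L <- stgee:::scenario_chol(sc)
  reps <- 40000
  set.seed(123)
  eps <- L %*% matrix(rnorm(nrow(lattice) * reps), nrow(lattice))
  d <- euclidean_distance_matrix(lattice)
  for (pair in list(c(1, 2), c(1, 5), c(3, 17))) {
    emp <- stats::cov(eps[pair[1], ], eps[pair[2], ])
    expect_equal(emp, sigma2 * exp(-d[pair[1], pair[2]] / kappa),
      tolerance = 4 * sigma2 / sqrt(reps) * 3
    )
  }
  expect_equal(stats::var(eps[7, ]), sigma2, tolerance = 0.05)
})
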