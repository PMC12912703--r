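test_that("m = 1 and m = n behave as the degenerate partitions", {
  coords <- generate_visium_lattice(3, 4)
  one <- kmeans_spatial(coords, 1, seed = 1)
  expect_equal(one$assignment, rep(1L, 12))
  expect_equal(one$centroids[1, ], c(mean(coords$x), mean(coords$y)),
    tolerance = 1e-12
  )
  all_own <- kmeans_spatial(coords, 12, seed = 1)
  expect_equal(sort(unique(all_own$assignment)), 1:12)
  expect_equal(all_own$wss, 0)
  expect_error(kmeans_spatial(coords, 13, seed = 1), class = "stgee_value_error")
})

test_that("two well-separated clouds are split along the gap (exhaustive oracle)", {
  set.seed(21)
  xy <- rbind(
    cbind(x = rnorm(5, 0, 0.2), y = rnorm(5, 0, 0.2)),
    cbind(x = rnorm(5, 10, 0.2), y = rnorm(5, 0, 0.2))
  )
  cl <- kmeans_spatial(xy, 2, seed = 3)
  expect_equal(length(unique(cl$assignment[1:5])), 1)
  expect_equal(length(unique(cl$assignment[6:10])), 1)
  expect_false(cl$assignment[1] == cl$assignment[6])
  expect_equal(cl$wss, exhaustive_kmeans_wss(xy, 2), tolerance = 1e-8)
})

test_that("solution matches the exhaustive optimum on small instances", {
  set.seed(22)
  for (k in 2:3) {
    xy <- cbind(x = runif(9, 0, 4), y = runif(9, 0, 4))
    cl <- kmeans_spatial(xy, k, seed = 5, n_restarts = 20)
    expect_equal(cl$wss, exhaustive_kmeans_wss(xy, k), tolerance = 1e-8)
  }
})

test_that("fixed seed gives bitwise-identical partitions and all clusters non-empty", {
  coords <- generate_visium_lattice(8, 8)
  a <- kmeans_spatial(coords, 7, seed = 99)
  b <- kmeans_spatial(coords, 7, seed = 99)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centroids, b$centroids)
  expect_equal(sort(unique(a$assignment)), 1:7)
  # never worse than stats::kmeans on the same instance (restart-selected WSS)
  ref <- stats::kmeans(as.matrix(coords[c("x", "y")]), 7, nstart = 10)
  expect_lt(a$wss, ref$tot.withinss * 1.05)
})

test_that("median split halves a region with |size difference| <= 1", {
  lab <- spatial_split(cbind(x = 1:4, y = 0), axis = "x")
  expect_equal(lab, c(0L, 0L, 1L, 1L))
  lab5 <- spatial_split(cbind(x = 1:5, y = 0), axis = "x")
  expect_equal(sum(lab5 == 0), 3) # tie/middle spot joins the lower half
  expect_equal(sum(lab5 == 1), 2)

  coords <- generate_visium_lattice(7, 9)
  mask <- coords$x > 4 # a corner region
  lab <- spatial_split(coords, subset_mask = mask, axis = "y")
  expect_true(all(is.na(lab[!mask])))
  expect_lte(abs(sum(lab == 0, na.rm = TRUE) - sum(lab == 1, na.rm = TRUE)), 1)
  expect_error(spatial_split(cbind(x = 1, y = 1)), class = "stgee_value_error")
})

test_that("half-split grade regions are connected on the lattice adjacency graph", {
  coords <- generate_visium_lattice(9, 10)
  lab <- assign_grades(coords, "spatial-half-split")
  d <- euclidean_distance_matrix(coords)
  adj <- d > 0 & d < 1.01 # nearest neighbours
  for (side in 0:1) {
    idx <- which(lab == side)
    visited <- rep(FALSE, length(idx))
    visited[1] <- TRUE
    frontier <- idx[1]
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(i) idx[adj[i, idx]])))
      new <- nxt[!visited[match(nxt, idx)]]
      visited[match(new, idx)] <- TRUE
      frontier <- new
    }
    expect_true(all(visited))
  }
})
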