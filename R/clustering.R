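#' Spatial K-means working clusters
#'
#' Partitions spots into `m` spatially contiguous working clusters by running
#' K-means on the raw spot coordinates (both axes share units on a Visium
#' lattice, so no standardization is applied). The clustering defines the
#' grouping over which the sandwich estimator blocks residuals
#' ([sandwich_covariance()]); it is a working device, not a biological
#' segmentation, and K-means' convex cells give the spatial contiguity the
#' device needs.
#'
#' Each restart is seeded with k-means++ and refined by Lloyd iterations
#' until the relative within-cluster sum-of-squares change falls below 1e-8
#' (at most 300 iterations); the restart with the lowest WSS wins. A cluster
#' that empties during iteration is re-seeded at the point farthest from its
#' assigned center, so all `m` clusters are always non-empty. Results are
#' deterministic given `(coords, m, seed, n_restarts)`.
#'
#' @param coords Spot coordinates (see [st_dataset()]) or an `st_dataset`.
#' @param m Number of working clusters, `1 <= m <= n` spots.
#' @param seed Integer seed controlling the k-means++ draws.
#' @param n_restarts Independent restarts (default 10).
#' @return A `working_clusters` object: list with `assignment` (integer
#'   vector in `1..m`), `m`, `centroids` (m x 2 matrix), `wss` (total
#'   within-cluster sum of squares).
#' @examples
#' coords <- generate_visium_lattice(6, 6)
#' cl <- kmeans_spatial(coords, m = 4, seed = 1)
#' table(cl$assignment)
#' @export
kmeans_spatial <- function(coords, m, seed = 1L, n_restarts = 10L) {
  if (inherits(coords, "st_dataset")) coords <- coords$coords
  xy <- as.matrix(canonical_coords(coords))
  n <- nrow(xy)
  m <- as.integer(m)
  if (m < 1 || m > n) {
    abort(sprintf("`m` must be in 1..%d (number of spots).", n),
      class = "stgee_value_error"
    )
  }
  if (m == n) {
    return(new_working_clusters(seq_len(n), m, xy, wss = 0))
  }
  best <- NULL
  rng <- local_rng(seed)
  for (r in seq_len(max(1L, as.integer(n_restarts)))) {
    centers <- kmeanspp_init(xy, m, rng)
    sol <- lloyd(xy, centers)
    if (is.null(best) || sol$wss < best$wss) best <- sol
  }
  new_working_clusters(best$assignment, m, best$centers, best$wss)
}

new_working_clusters <- function(assignment, m, centroids, wss) {
  structure(
    list(
      assignment = as.integer(assignment), m = as.integer(m),
      centroids = unname(as.matrix(centroids)), wss = wss
    ),
    class = "working_clusters"
  )
}

#' @export
print.working_clusters <- function(x, ...) {
  cat(sprintf(
    "<working_clusters> %d spots in %d clusters (sizes %s..%s), WSS = %.4g\n",
    length(x$assignment), x$m, min(tabulate(x$assignment, x$m)),
    max(tabulate(x$assignment, x$m)), x$wss
  ))
  invisible(x)
}

# private RNG stream: draws do not disturb the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  }
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- expr()
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
}

kmeanspp_init <- function(xy, m, rng) {
  n <- nrow(xy)
  centers <- matrix(0, m, ncol(xy))
  first <- rng(function() sample.int(n, 1L))
  centers[1, ] <- xy[first, ]
  d2 <- rowSums((xy - rep(centers[1, ], each = n))^2)
  if (m > 1) {
    for (k in 2:m) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- rng(function() sample.int(n, 1L, prob = probs))
      centers[k, ] <- xy[idx, ]
      d2 <- pmin(d2, rowSums((xy - rep(centers[k, ], each = n))^2))
    }
  }
  centers
}

lloyd <- function(xy, centers, tol = 1e-8, max_iter = 300L) {
  n <- nrow(xy)
  m <- nrow(centers)
  wss_old <- Inf
  assignment <- integer(n)
  for (iter in seq_len(max_iter)) {
    # squared distances spot x center
    d2 <- outer(rowSums(xy^2), rep(1, m)) - 2 * xy %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    assignment <- max.col(-d2, ties.method = "first")
    # farthest-point repair keeps all m clusters populated
    empties <- setdiff(seq_len(m), unique(assignment))
    for (k in empties) {
      nearest <- d2[cbind(seq_len(n), assignment)]
      far <- which.max(nearest)
      assignment[far] <- k
      nearest[far] <- 0
    }
    for (k in seq_len(m)) {
      centers[k, ] <- colMeans(xy[assignment == k, , drop = FALSE])
    }
    wss <- sum((xy - centers[assignment, , drop = FALSE])^2)
    if (is.finite(wss_old) && abs(wss_old - wss) <= tol * max(wss_old, 1e-12)) break
    wss_old <- wss
  }
  list(assignment = assignment, centers = centers, wss = wss)
}

#' Median split of a spot subset into two pseudo-groups
#'
#' Splits a region of the slide at the median of one coordinate into two
#' near-equal halves, producing control-vs-control pseudo-grades for
#' negative-control scans (e.g. splitting a histologically uniform fibrous
#' region into FT1 vs FT2 and scanning FT1 against FT2, where any
#' significant gene is a presumptive false positive). Spots tied at the
#' median go to the lower half until the halves differ by at most one spot.
#'
#' @param coords Spot coordinates or an `st_dataset`.
#' @param subset_mask Logical/integer selector of the spots to split
#'   (default: all spots).
#' @param axis `"x"` or `"y"`: the coordinate to split on.
#' @return Integer vector over all spots: `NA` outside the subset, 0 for the
#'   lower half, 1 for the upper half.
#' @examples
#' spatial_split(cbind(x = 1:4, y = 0), axis = "x")
#' @export
spatial_split <- function(coords, subset_mask = NULL, axis = c("x", "y")) {
  if (inherits(coords, "st_dataset")) coords <- coords$coords
  axis <- match.arg(axis)
  xy <- canonical_coords(coords)
  n <- nrow(xy)
  idx <- if (is.null(subset_mask)) seq_len(n) else seq_len(n)[subset_mask]
  if (length(idx) < 2) {
    abort("subset must contain at least 2 spots.", class = "stgee_value_error")
  }
  v <- xy[[axis]][idx]
  ord <- order(v, idx[seq_along(v)] * 0 + seq_along(v)) # stable order along axis
  n_low <- ceiling(length(idx) / 2) # tie spot joins the lower half
  lab <- integer(length(idx))
  lab[ord[seq_len(n_low)]] <- 0L
  lab[ord[-seq_len(n_low)]] <- 1L
  out <- rep(NA_integer_, n)
  out[idx] <- lab
  out
}
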