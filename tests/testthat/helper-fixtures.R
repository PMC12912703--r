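# in-code fixtures shared across test files

# small dataset with both grades and a mix of sparse/dense genes
make_test_dataset <- function(n_genes = 6, n_spots = 24, seed = 42) {
  set.seed(seed)
  lattice <- generate_visium_lattice(4, n_spots / 4)
  counts <- matrix(rpois(n_genes * n_spots, lambda = rep(c(0.2, 2, 8), length.out = n_genes)),
    nrow = n_genes
  )
  st_dataset(
    counts = counts, coords = lattice,
    labels = assign_grades(lattice), # half split
    gene_ids = sprintf("g%02d", seq_len(n_genes)),
    spot_ids = sprintf("s%02d", seq_len(n_spots))
  )
}

# exact Wilcoxon p-value by enumeration of all C(N, nx) rank assignments
# (tie-free samples only); two-sided via statistic symmetry
exact_wilcoxon_p <- function(x, y) {
  n <- length(x) + length(y)
  nx <- length(x)
  r <- rank(c(x, y))
  wx_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  all_wx <- apply(utils::combn(n, nx), 2, sum)
  mean(abs(all_wx - mu) >= abs(wx_obs - mu))
}

# brute-force BH step-up on a p vector without NAs
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive minimal within-cluster SS over all assignments of n points to
# k non-empty clusters (tiny n only)
exhaustive_kmeans_wss <- function(xy, k) {
  n <- nrow(xy)
  best <- Inf
  assign_next <- function(assignment, i) {
    if (i > n) {
      if (length(unique(assignment)) == k) {
        wss <- 0
        for (c in unique(assignment)) {
          pts <- xy[assignment == c, , drop = FALSE]
          ctr <- colMeans(pts)
          wss <- wss + sum((pts - rep(ctr, each = nrow(pts)))^2)
        }
        best <<- min(best, wss)
      }
      return(invisible())
    }
    upper <- min(max(assignment[seq_len(i - 1)], 0) + 1, k)
    for (c in seq_len(upper)) {
      assignment[i] <- c
      assign_next(assignment, i + 1)
    }
  }
  assign_next(integer(n), 1)
  best
}
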