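#' Hexagonally offset Visium-like spot lattice
#'
#' Builds the synthetic slide geometry used by the simulator: a hex-packed
#' grid with odd rows shifted half a unit and row spacing `sqrt(3)/2`, so
#' every spot's nearest neighbours sit at distance 1 (one nearest-neighbour
#' spacing is the coordinate unit throughout the package). A 59 x 59 lattice
#' (3,481 spots) is the default stand-in for a full Visium capture area.
#'
#' @param n_rows,n_cols Lattice dimensions (each at least 1).
#' @return Tibble with columns `x`, `y`, `row`, `col`; `n_rows * n_cols` rows.
#' @examples
#' generate_visium_lattice(2, 2)
#' @export
generate_visium_lattice <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  tibble(
    x = col + 0.5 * (row %% 2L),
    y = row * sqrt(3) / 2,
    row = row, col = col
  )
}

#' Exponential spatial covariance matrix
#'
#' `V[i, i'] = sigma2 * exp(-tau_ii' / kappa)` with `tau` the Euclidean
#' distance between spots: the Matern covariance at smoothness 0.5. `kappa`
#' is the correlation decay length in coordinate units (larger values mean
#' longer-ranged correlation); `sigma2` the marginal variance of the latent
#' log-intensity field. `sigma2 = 0` gives the independence limit.
#'
#' @param coords Spot coordinates (see [st_dataset()]).
#' @param sigma2 Spatial variance, `>= 0`.
#' @param kappa Decay length, `> 0`, in coordinate units.
#' @return Dense symmetric covariance matrix.
#' @examples
#' build_spatial_covariance(generate_visium_lattice(2, 2), sigma2 = 1, kappa = 2)
#' @export
build_spatial_covariance <- function(coords, sigma2, kappa) {
  if (sigma2 < 0) abort("`sigma2` must be >= 0.", class = "stgee_value_error")
  if (kappa <= 0) abort("`kappa` must be > 0.", class = "stgee_value_error")
  d <- euclidean_distance_matrix(coords)
  sigma2 * exp(-d / kappa)
}

#' Assign binary grades to simulated spots
#'
#' Two layouts for the simulated pathology grades: `"spatial-half-split"`
#' (default) labels the half of the slide with the larger x coordinate as
#' grade B, producing two contiguous regions like adjacent pathology grades;
#' `"random-balanced"` scatters the grade randomly. Both yield groups whose
#' sizes differ by at most one spot.
#'
#' @param coords Spot coordinates.
#' @param grade_scheme `"spatial-half-split"` or `"random-balanced"`.
#' @param seed Integer seed (used by the random scheme only).
#' @return Integer 0/1 vector, one per spot.
#' @examples
#' assign_grades(generate_visium_lattice(4, 4))
#' @export
assign_grades <- function(coords, grade_scheme = c("spatial-half-split", "random-balanced"),
                          seed = 1L) {
  grade_scheme <- match.arg(grade_scheme)
  xy <- canonical_coords(coords)
  n <- nrow(xy)
  if (n < 2) abort("need at least 2 spots.", class = "stgee_value_error")
  if (grade_scheme == "spatial-half-split") {
    return(spatial_split(xy, axis = "x"))
  }
  rng <- local_rng(seed)
  perm <- rng(function() sample.int(n))
  lab <- integer(n)
  lab[perm[seq_len(ceiling(n / 2))]] <- 0L
  lab[perm[-seq_len(ceiling(n / 2))]] <- 1L
  lab
}

#' Define a Poisson log-normal spatial simulation scenario
#'
#' A scenario fixes the generative model for one simulated gene:
#' counts `Y_i ~ Poisson(mu_i)` given a latent Gaussian field, with
#' `log mu_i = beta0 + beta1 * X_i + eps_i` and
#' `eps ~ N(0, sigma2 * exp(-tau / kappa))` (exponential kernel, the Matern
#' family at smoothness 0.5). A small intercept `beta0` induces the
#' zero inflation characteristic of spot-level counts; `beta1 = 0` is the
#' null of no differential expression. The Cholesky factor of the covariance
#' is computed once per scenario and cached.
#'
#' @param sigma2 Spatial variance (`>= 0`; 0 gives independent Poisson noise).
#' @param kappa Correlation decay length (`> 0`, coordinate units).
#' @param beta0 Log-scale intercept; the preset `-2.5` puts over 90% of spots
#'   at zero under the null.
#' @param beta1 Grade-B log fold change (0 under the null).
#' @param lattice Spot coordinates: a tibble from
#'   [generate_visium_lattice()], any coordinate table, or an `st_dataset`
#'   whose coordinates are reused.
#' @param grade_scheme Passed to [assign_grades()].
#' @param seed Integer seed; [simulate_gene()] is deterministic given the
#'   scenario.
#' @return A `sim_scenario` object (list with the parameters, `coords`,
#'   `labels`, and a Cholesky cache).
#' @examples
#' sc <- st_scenario(sigma2 = 1, kappa = 2, lattice = generate_visium_lattice(8, 8))
#' table(simulate_gene(sc))
#' @export
st_scenario <- function(sigma2, kappa, beta0 = -2.5, beta1 = 0,
                        lattice = generate_visium_lattice(59, 59),
                        grade_scheme = c("spatial-half-split", "random-balanced"),
                        seed = 1L) {
  if (inherits(lattice, "st_dataset")) lattice <- lattice$coords
  grade_scheme <- match.arg(grade_scheme)
  coords <- canonical_coords(lattice)
  if (nrow(coords) < 2) abort("lattice needs >= 2 spots.", class = "stgee_value_error")
  if (sigma2 < 0) abort("`sigma2` must be >= 0.", class = "stgee_value_error")
  if (kappa <= 0) abort("`kappa` must be > 0.", class = "stgee_value_error")
  labels <- assign_grades(coords, grade_scheme, seed = seed)
  structure(
    list(
      sigma2 = sigma2, kappa = kappa, beta0 = beta0, beta1 = beta1,
      nu = 0.5, coords = coords, labels = labels,
      grade_scheme = grade_scheme, seed = as.integer(seed),
      cache = new.env(parent = emptyenv())
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %d spots | sigma2 = %g, kappa = %g, beta0 = %g, beta1 = %g | %s\n",
    nrow(x$coords), x$sigma2, x$kappa, x$beta0, x$beta1, x$grade_scheme
  ))
  invisible(x)
}

# lower-triangular Cholesky factor of the scenario covariance, cached.
# a 1e-10 diagonal jitter is added (once, escalating to 1e-8/1e-6) if the
# kernel matrix is numerically semidefinite.
scenario_chol <- function(scenario) {
  if (!is.null(scenario$cache$L)) {
    return(scenario$cache$L)
  }
  n <- nrow(scenario$coords)
  if (scenario$sigma2 == 0) {
    L <- NULL # independence limit: no latent field
  } else {
    v <- build_spatial_covariance(scenario$coords, scenario$sigma2, scenario$kappa)
    L <- NULL
    for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
      r <- tryCatch(chol(v + diag(jit, n)), error = function(e) NULL)
      if (!is.null(r)) {
        L <- t(r)
        break
      }
    }
    if (is.null(L)) {
      abort("covariance matrix is not positive definite even after jitter.",
        class = "stgee_numerical_error"
      )
    }
  }
  scenario$cache$L <- L
  L
}

# deterministic sub-seed for (replicate, stage) streams; stays below 2^31-1
derive_seed <- function(seed, r, stage = 1L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 16807 +
    as.numeric(stage) * 69621) %% 2147483647)
}

#' Simulate one gene from a scenario
#'
#' Draws the latent field `eps = L z` with `z ~ N(0, I)` (L the cached
#' Cholesky factor), then counts by inverse-CDF Poisson sampling
#' `Y_i = qpois(u_i, exp(beta0 + beta1 X_i + eps_i))` with `u ~ U(0, 1)`,
#' so counts are independent given the field. Deterministic given
#' `(scenario, seed)`.
#'
#' @param scenario A [st_scenario()].
#' @param seed Replicate seed; defaults to the scenario seed.
#' @return Integer count vector, one per spot.
#' @export
simulate_gene <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  drop(simulate_gene_matrix(scenario, n_reps = 1L, seed = seed, offset = 0L))
}

#' Simulate many replicate genes from a scenario
#'
#' Vectorized form of [simulate_gene()]: replicate `r` uses the derived seed
#' stream for `offset + r`, so a block of replicates is reproducible
#' independently of how it is chunked.
#'
#' @inheritParams simulate_gene
#' @param n_reps Number of replicate genes.
#' @param offset Replicate index offset (for chunked generation).
#' @return Integer matrix, spots x replicates.
#' @export
simulate_genes <- function(scenario, n_reps, seed = scenario$seed, offset = 0L) {
  simulate_gene_matrix(scenario, n_reps, seed, offset)
}

simulate_gene_matrix <- function(scenario, n_reps, seed, offset = 0L) {
  n <- nrow(scenario$coords)
  L <- scenario_chol(scenario)
  z <- matrix(0, n, n_reps)
  u <- matrix(0, n, n_reps)
  for (r in seq_len(n_reps)) {
    rr <- local_rng(derive_seed(seed, offset + r))
    z[, r] <- rr(function() rnorm(n))
    u[, r] <- rr(function() runif(n))
  }
  eta <- scenario$beta0 + scenario$beta1 * scenario$labels
  if (is.null(L)) {
    lambda <- exp(eta)
    y <- stats::qpois(u, rep(lambda, times = n_reps))
  } else {
    eps <- L %*% z
    y <- stats::qpois(u, exp(eta + eps))
  }
  storage.mode(y) <- "integer"
  dim(y) <- c(n, n_reps)
  y
}
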