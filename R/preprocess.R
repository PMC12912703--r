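#' Quality-control and gene-selection configuration
#'
#' Bundles the preprocessing knobs with their package defaults:
#' spots with fewer than `min_total_counts_per_spot` total counts are
#' dropped, genes detected in fewer than `min_spots_per_gene` spots are
#' dropped, and the `n_hvg` most variable genes are retained. The filters
#' are applied sequentially, in that order, each to the current matrix.
#'
#' @param min_total_counts_per_spot Non-negative integer (default 500).
#' @param min_spots_per_gene Non-negative integer (default 10).
#' @param n_hvg Positive integer (default 3000).
#' @return A named list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_total_counts_per_spot = 500,
                              min_spots_per_gene = 10,
                              n_hvg = 3000) {
  stopifnot(
    min_total_counts_per_spot >= 0, min_spots_per_gene >= 0,
    n_hvg >= 1
  )
  structure(
    list(
      min_total_counts_per_spot = min_total_counts_per_spot,
      min_spots_per_gene = min_spots_per_gene, n_hvg = n_hvg
    ),
    class = "preprocess_config"
  )
}

subset_dataset <- function(dataset, genes = NULL, spots = NULL) {
  genes <- genes %||% seq_len(nrow(dataset$counts))
  spots <- spots %||% seq_len(ncol(dataset$counts))
  st_dataset(
    counts = dataset$counts[genes, spots, drop = FALSE],
    coords = dataset$coords[spots, , drop = FALSE],
    labels = dataset$labels[spots],
    gene_ids = dataset$gene_ids[genes],
    spot_ids = dataset$spot_ids[spots]
  )
}

#' Drop spots with low total counts
#'
#' @param dataset An [st_dataset()].
#' @param min_total_counts_per_spot Spots whose column total is below this
#'   threshold are removed; the gene set is unchanged.
#' @return Filtered [st_dataset()]; an error if no spot survives.
#' @export
filter_spots <- function(dataset, min_total_counts_per_spot = 500) {
  stopifnot(inherits(dataset, "st_dataset"))
  keep <- which(Matrix::colSums(dataset$counts) >= min_total_counts_per_spot)
  if (length(keep) == 0) {
    abort("spot filter removed every spot.", class = "stgee_value_error")
  }
  if (length(keep) < ncol(dataset$counts)) {
    inform(sprintf(
      "filter_spots: %d of %d spots removed (total counts < %g).",
      ncol(dataset$counts) - length(keep), ncol(dataset$counts),
      min_total_counts_per_spot
    ))
  }
  subset_dataset(dataset, spots = keep)
}

#' Drop genes detected in too few spots
#'
#' @param dataset An [st_dataset()].
#' @param min_spots_per_gene Genes with a nonzero count in fewer than this
#'   many spots are removed.
#' @return Filtered [st_dataset()]; an error if no gene survives.
#' @export
filter_genes <- function(dataset, min_spots_per_gene = 10) {
  stopifnot(inherits(dataset, "st_dataset"))
  detected <- Matrix::rowSums(dataset$counts > 0)
  keep <- which(detected >= min_spots_per_gene)
  if (length(keep) == 0) {
    abort("gene filter removed every gene.", class = "stgee_value_error")
  }
  if (length(keep) < nrow(dataset$counts)) {
    inform(sprintf(
      "filter_genes: %d of %d genes removed (detected in < %g spots).",
      nrow(dataset$counts) - length(keep), nrow(dataset$counts),
      min_spots_per_gene
    ))
  }
  subset_dataset(dataset, genes = keep)
}

#' Per-gene variability score used by [select_hvg()]
#'
#' Variance across spots of `log1p` of counts normalized to the median
#' library size: each spot's counts are scaled to a common depth
#' (`median(total counts)`), log-transformed with `log1p`, and the per-gene
#' variance of the result is the score.
#'
#' @param dataset An [st_dataset()].
#' @return Numeric vector, one score per gene.
#' @export
hvg_scores <- function(dataset) {
  stopifnot(inherits(dataset, "st_dataset"))
  totals <- Matrix::colSums(dataset$counts)
  depth <- median(totals)
  sf <- ifelse(totals > 0, depth / totals, 0)
  norm <- as.matrix(dataset$counts)
  norm <- norm * rep(sf, each = nrow(norm))
  logn <- log1p(norm)
  # rowwise variance without a per-gene loop
  mu <- rowMeans(logn)
  rowSums((logn - mu)^2) / (ncol(logn) - 1)
}

#' Select highly variable genes
#'
#' Restricts the dataset to the `n_hvg` genes with the largest
#' [hvg_scores()] (ties broken by input order), preserving the input gene
#' order among those retained. Genome-wide scans conventionally run on the
#' 3,000 most variable genes.
#'
#' @param dataset An [st_dataset()].
#' @param n_hvg Number of genes to keep (at most the current gene count).
#' @return Filtered [st_dataset()] with exactly `n_hvg` genes.
#' @export
select_hvg <- function(dataset, n_hvg = 3000) {
  stopifnot(inherits(dataset, "st_dataset"))
  if (n_hvg > nrow(dataset$counts)) {
    abort(sprintf(
      "`n_hvg` (%d) exceeds the number of genes (%d).",
      n_hvg, nrow(dataset$counts)
    ), class = "stgee_value_error")
  }
  sc <- hvg_scores(dataset)
  top <- sort(order(sc, decreasing = TRUE)[seq_len(n_hvg)])
  subset_dataset(dataset, genes = top)
}

#' Zero-fraction sparsity summaries
#'
#' Per-gene and per-spot fractions of zero entries, the diagnostics used to
#' compare simulated and real data sparsity (spot-level counts typically
#' show 70-90% zeros per spot; the zero-inflation simulator preset exceeds
#' 90%).
#'
#' @param dataset An [st_dataset()].
#' @return A list with tibbles `per_gene` (`gene_id`, `zero_fraction`) and
#'   `per_spot` (`spot_id`, `zero_fraction`), plus `gene_quartiles` and
#'   `spot_quartiles` (numeric, quartiles 0/25/50/75/100%).
#' @export
sparsity_summary <- function(dataset) {
  stopifnot(inherits(dataset, "st_dataset"))
  n_spots <- ncol(dataset$counts)
  n_genes <- nrow(dataset$counts)
  gene_zero <- 1 - Matrix::rowSums(dataset$counts > 0) / n_spots
  spot_zero <- 1 - Matrix::colSums(dataset$counts > 0) / n_genes
  list(
    per_gene = tibble(gene_id = dataset$gene_ids, zero_fraction = as.numeric(gene_zero)),
    per_spot = tibble(spot_id = dataset$spot_ids, zero_fraction = as.numeric(spot_zero)),
    gene_quartiles = stats::quantile(gene_zero, c(0, 0.25, 0.5, 0.75, 1)),
    spot_quartiles = stats::quantile(spot_zero, c(0, 0.25, 0.5, 0.75, 1))
  )
}
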