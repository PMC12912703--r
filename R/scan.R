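#' Genome-wide differential expression scan
#'
#' Applies one of the five tests independently to every gene of a dataset,
#' comparing grade B against grade A spots, and returns a per-gene results
#' table with BH (FDR) and Bonferroni (FWER) adjusted p-values and the
#' gene's zero fraction. Genes with degenerate input or nonconvergent fits
#' are flagged in `status` and carry missing p-values; they are excluded
#' from the number of tests M used by both corrections rather than dropped
#' silently.
#'
#' For the clustered GEE tests pass either a precomputed
#' [kmeans_spatial()] partition via `clusters` or a cluster count via `m`
#' (the partition is then computed from the dataset coordinates with
#' `seed`).
#'
#' @param dataset An [st_dataset()] with both grades present.
#' @param method One of [st_test_methods()].
#' @param clusters Optional [kmeans_spatial()] result or assignment vector.
#' @param m Optional number of spatial working clusters (used when
#'   `clusters` is `NULL`).
#' @param seed Seed for the K-means partition when computed here.
#' @param values Optional numeric matrix (same shape as the counts) to test
#'   instead of the raw counts — e.g. a normalized/transformed expression
#'   matrix for the rank-sum or z-test. The GEE tests are count models and
#'   always use raw counts.
#' @return A `scan_result` tibble: `gene_id`, `method`, `statistic`,
#'   `p_value`, `p_bh`, `p_bonferroni`, `status`, `zero_fraction`.
#' @examples
#' sc <- scenario_preset("independent", n_rows = 6, n_cols = 6)
#' Y <- simulate_genes(sc, 20)
#' ds <- st_dataset(t(Y), sc$coords, sc$labels)
#' scan_genes(ds, method = "wilcoxon")
#' @export
scan_genes <- function(dataset, method = c(
                         "wilcoxon", "ztest", "gee-wald",
                         "gee-gst", "independent-gee"
                       ),
                       clusters = NULL, m = NULL, seed = 1L, values = NULL) {
  stopifnot(inherits(dataset, "st_dataset"))
  method <- match.arg(method)
  if (length(unique(dataset$labels)) < 2) {
    abort("both grades must be present for a two-group scan.",
      class = "stgee_value_error"
    )
  }
  if (method %in% c("gee-wald", "gee-gst")) {
    if (is.null(clusters)) {
      if (is.null(m)) {
        abort("clustered GEE scans need `clusters` or `m`.",
          class = "stgee_value_error"
        )
      }
      clusters <- kmeans_spatial(dataset$coords, m = m, seed = seed)
    }
  } else {
    clusters <- NULL
  }
  counts <- as.matrix(dataset$counts)
  Y <- if (!is.null(values) && method %in% c("wilcoxon", "ztest")) {
    stopifnot(all(dim(values) == dim(counts)))
    as.matrix(values)
  } else {
    counts
  }
  # genes are columns of the batch engine's replicate matrix
  res <- batch_test_matrix(t(Y), dataset$labels, method, clusters = clusters)
  zf <- as.numeric(1 - Matrix::rowSums(dataset$counts > 0) / ncol(dataset$counts))
  out <- tibble(
    gene_id = dataset$gene_ids, method = method,
    statistic = res$statistic, p_value = res$p_value,
    p_bh = adjust_pvalues(res$p_value, "BH"),
    p_bonferroni = adjust_pvalues(res$p_value, "bonferroni"),
    status = res$status, zero_fraction = zf
  )
  structure(out, class = c("scan_result", class(out)))
}

#' Multiple-testing adjustment with missing-value handling
#'
#' Benjamini-Hochberg step-up (FDR) or Bonferroni (FWER) adjustment.
#' Missing p-values — nonconvergent or degenerate genes — are excluded from
#' the number of tests M and propagated as missing, so failures do not bias
#' the adjusted values of the remaining genes.
#'
#' @param p_vector Numeric p-values in `[0, 1]`, `NA` allowed.
#' @param procedure `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and `NA` pattern as the input.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH")
#' @export
adjust_pvalues <- function(p_vector, procedure = c("BH", "bonferroni")) {
  procedure <- match.arg(procedure)
  ok <- !is.na(p_vector)
  if (any(p_vector[ok] < 0 | p_vector[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "stgee_value_error")
  }
  out <- rep(NA_real_, length(p_vector))
  out[ok] <- stats::p.adjust(p_vector[ok], method = procedure)
  out
}

#' Expected-vs-observed quantiles for a QQ plot of p-values
#'
#' Sorts the observed p-values and pairs `-log10(p_(k))` with the uniform
#' order-statistic expectation `-log10(k / (M + 1))`. Underflowed p-values
#' (p = 0) are capped at `-log10(p) = 320`. Under a global null the points
#' lie on the identity line; systematic elevation indicates inflated
#' (anti-conservative) p-values.
#'
#' @param p_vector Numeric p-values; `NA` entries are dropped.
#' @return Tibble with columns `expected`, `observed` (both `-log10`
#'   scale), sorted by `expected` descending significance.
#' @examples
#' qq_data(runif(100))
#' @export
qq_data <- function(p_vector) {
  p <- p_vector[!is.na(p_vector)]
  if (length(p) < 1) abort("need at least one p-value.", class = "stgee_value_error")
  m <- length(p)
  obs <- -log10(sort(p))
  obs[!is.finite(obs) | obs > 320] <- 320
  tibble(expected = -log10(seq_len(m) / (m + 1)), observed = obs)
}

#' Sparsity-stratified QQ data and p-value histograms
#'
#' Groups a scan's genes by their zero fraction and returns per-bin QQ
#' coordinates and 20-bin p-value histograms, the diagnostic that localizes
#' p-value miscalibration to the non-sparse genes for which spatial
#' correlation bites hardest.
#'
#' @param scan_result A [scan_genes()] result.
#' @param zero_fraction_bins Increasing break points covering `[0, 1]`
#'   (default quartile bins `0, .25, .5, .75, 1`).
#' @return Tibble with one row per bin: `bin` (label), `n_genes`, and
#'   list-columns `qq` (tibble as [qq_data()]) and `histogram` (tibble with
#'   `mid`, `count` over 20 equal-width p bins). Empty bins keep zero rows.
#' @export
stratified_summary <- function(scan_result, zero_fraction_bins = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is.data.frame(scan_result))
  br <- zero_fraction_bins
  if (is.unsorted(br, strictly = TRUE) || br[1] > 0 || br[length(br)] < 1) {
    abort("`zero_fraction_bins` must be strictly increasing and cover [0, 1].",
      class = "stgee_value_error"
    )
  }
  bin <- cut(scan_result$zero_fraction, br, include.lowest = TRUE, right = FALSE)
  # make the top bin closed on the right: zero fraction 1 belongs to the last bin
  bin[scan_result$zero_fraction >= br[length(br) - 1]] <- levels(bin)[length(levels(bin))]
  purrr::map_dfr(levels(bin), function(lv) {
    p <- scan_result$p_value[which(bin == lv)]
    p <- p[!is.na(p)]
    hist_counts <- if (length(p)) {
      tabulate(pmin(floor(p * 20) + 1, 20), nbins = 20)
    } else {
      integer(20)
    }
    tibble(
      bin = lv, n_genes = length(p),
      qq = list(if (length(p)) qq_data(p) else tibble(expected = numeric(), observed = numeric())),
      histogram = list(tibble(mid = (seq_len(20) - 0.5) / 20, count = hist_counts))
    )
  })
}
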