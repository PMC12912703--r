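#' Assemble and validate a spatial transcriptomics dataset
#'
#' Bundles a gene-by-spot count matrix with spot coordinates and a binary
#' pathology-grade label per spot into a validated `st_dataset` object, the
#' input container for every scan and test in the package. Grade labels follow
#' the two-group convention used throughout: 0 for the reference region
#' ("Grade A") and 1 for the comparison region ("Grade B").
#'
#' @param counts Non-negative integer matrix (base or `Matrix` sparse),
#'   genes in rows and spots in columns.
#' @param coords Data frame or matrix of planar spot positions; the first two
#'   numeric columns (or columns named `x`, `y`) are used, in spot-center
#'   units. One row per spot, in column order of `counts`.
#' @param labels Per-spot grade indicator: values in `{0, 1}` (integers,
#'   logicals, or a factor/character with exactly two levels, mapped to 0/1
#'   by sort order).
#' @param gene_ids,spot_ids Unique identifier vectors; default to the
#'   dimnames of `counts`, or generated identifiers when absent.
#'
#' @return An `st_dataset`: a list with elements `counts`, `coords` (tibble
#'   with columns `x`, `y`), `labels` (integer 0/1), `gene_ids`, `spot_ids`.
#'
#' @examples
#' counts <- matrix(rpois(8, 2), nrow = 2)
#' ds <- st_dataset(counts, cbind(x = 1:4, y = 0), labels = c(0, 0, 1, 1))
#' ds
#' @export
st_dataset <- function(counts, coords, labels, gene_ids = NULL, spot_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!(is.matrix(counts) || inherits(counts, "Matrix"))) {
    abort("`counts` must be a matrix (genes x spots).", class = "stgee_shape_error")
  }
  coords <- canonical_coords(coords)
  if (ncol(counts) != nrow(coords)) {
    abort(sprintf(
      "`counts` has %d spots (columns) but `coords` has %d rows.",
      ncol(counts), nrow(coords)
    ), class = "stgee_shape_error")
  }
  labels <- canonical_labels(labels)
  if (length(labels) != ncol(counts)) {
    abort(sprintf(
      "`counts` has %d spots but `labels` has length %d.",
      ncol(counts), length(labels)
    ), class = "stgee_shape_error")
  }
  if (min_count(counts) < 0) {
    abort("`counts` contains negative entries.", class = "stgee_value_error")
  }
  gene_ids <- gene_ids %||% rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts)))
  spot_ids <- spot_ids %||% colnames(counts) %||% sprintf("spot%d", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != nrow(counts) || length(spot_ids) != ncol(counts)) {
    abort("identifier lengths do not match `counts` dimensions.",
      class = "stgee_shape_error"
    )
  }
  if (anyDuplicated(gene_ids)) abort("`gene_ids` contains duplicates.", class = "stgee_value_error")
  if (anyDuplicated(spot_ids)) abort("`spot_ids` contains duplicates.", class = "stgee_value_error")
  if (length(unique(labels)) < 2L) {
    # a single-grade dataset is still usable for simulation under the null;
    # two-group tests check this again and refuse
    inform("all spots carry the same grade label; two-group tests will be unavailable.")
  }
  dimnames(counts) <- list(gene_ids, spot_ids)
  structure(
    list(
      counts = counts, coords = coords, labels = labels,
      gene_ids = gene_ids, spot_ids = spot_ids
    ),
    class = "st_dataset"
  )
}

min_count <- function(counts) {
  if (inherits(counts, "sparseMatrix")) {
    x <- counts@x
    if (length(x) == 0) 0 else min(x, 0)
  } else {
    if (length(counts) == 0) 0 else min(counts)
  }
}

canonical_coords <- function(coords) {
  if (is.null(dim(coords))) {
    abort("`coords` must have two columns (x, y).", class = "stgee_shape_error")
  }
  coords <- as.data.frame(coords)
  if (all(c("x", "y") %in% names(coords))) {
    coords <- coords[c("x", "y")]
  } else {
    num <- vapply(coords, is.numeric, logical(1))
    if (sum(num) < 2) abort("`coords` needs two numeric columns.", class = "stgee_shape_error")
    coords <- coords[which(num)[1:2]]
    names(coords) <- c("x", "y")
  }
  if (anyNA(coords)) abort("`coords` contains missing values.", class = "stgee_value_error")
  tibble::as_tibble(coords)
}

canonical_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) > 2) {
      abort("`labels` must have at most two distinct values.", class = "stgee_value_error")
    }
    labels <- as.integer(match(as.character(labels), lev) - 1L)
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("`labels` must be binary (0/1).", class = "stgee_value_error")
  }
  labels
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf(
    "<st_dataset> %d genes x %d spots (grade A: %d, grade B: %d spots)\n",
    nrow(x$counts), ncol(x$counts), sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

#' Pairwise Euclidean distances between spots
#'
#' Distances are unscaled Euclidean in whatever unit the coordinates carry
#' (spot-center units for Visium lattices); the spatial decay parameter
#' `kappa` of the simulator is expressed in the same unit.
#'
#' @param coords Data frame/matrix of planar positions (see [st_dataset()]),
#'   or an `st_dataset` whose coordinates are used.
#' @return Dense symmetric matrix with zero diagonal, `n x n` for `n` spots.
#' @examples
#' euclidean_distance_matrix(cbind(x = c(0, 3), y = c(0, 4)))
#' @export
euclidean_distance_matrix <- function(coords) {
  if (inherits(coords, "st_dataset")) coords <- coords$coords
  coords <- canonical_coords(coords)
  if (nrow(coords) < 1) abort("need at least one spot.", class = "stgee_value_error")
  d <- as.matrix(dist(as.matrix(coords)))
  dimnames(d) <- NULL
  d
}

#' One-row tibble describing a test outcome
#'
#' All hypothesis tests in the package return this shape: the standardized
#' statistic, its two-sided normal p-value, the method tag, and a status flag.
#' The p-value is present when `status == "ok"`, and for degenerate inputs
#' whose limiting p-value is well defined (an all-tied sample: p = 1, no
#' evidence). Nonconvergent fits and undefined degenerate cases carry `NA`
#' p-values so they can be excluded from multiple-testing corrections rather
#' than silently counted.
#'
#' @param method Method tag, one of [st_test_methods()].
#' @param statistic Standardized statistic (may be `NA` on failure).
#' @param p_value Two-sided p-value in `[0, 1]`, or `NA`.
#' @param status `"ok"`, `"degenerate_input"`, or `"nonconvergence"`.
#' @return A one-row tibble with columns `method`, `statistic`, `p_value`,
#'   `status`.
#' @keywords internal
#' @export
test_result <- function(method, statistic, p_value, status = "ok") {
  status <- match.arg(status, c("ok", "degenerate_input", "nonconvergence"))
  if (status == "ok") {
    stopifnot(!is.na(p_value), p_value >= 0, p_value <= 1)
  } else if (status == "nonconvergence") {
    p_value <- NA_real_
  } else if (!is.na(p_value)) {
    stopifnot(p_value >= 0, p_value <= 1)
  }
  tibble(
    method = method, statistic = as.numeric(statistic),
    p_value = as.numeric(p_value), status = status
  )
}

#' Method tags understood by the scan and benchmark drivers
#'
#' @return Character vector of the five supported tests.
#' @export
st_test_methods <- function() {
  c("wilcoxon", "ztest", "gee-wald", "gee-gst", "independent-gee")
}
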