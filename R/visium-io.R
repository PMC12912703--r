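#' Read a 10x Visium-style dataset
#'
#' Assembles an [st_dataset()] from the standard Visium triplet layout: a
#' MatrixMarket count matrix with features/barcodes TSVs, a
#' `tissue_positions` CSV, and a per-spot grade label TSV. The dataset is
#' restricted to barcodes present in all three sources (spots dropped from
#' any source are counted in a message); genes stay in matrix order.
#'
#' Both Space Ranger positions dialects are understood: the headerless v1
#' CSV and the headered v2 CSV, each with columns barcode, in_tissue,
#' array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres. All files
#' may be gzip-compressed (`.gz`).
#'
#' @param matrix_dir Directory containing `matrix.mtx(.gz)`,
#'   `features.tsv(.gz)` (or `genes.tsv`), `barcodes.tsv(.gz)`.
#' @param positions_path Path to the tissue positions CSV.
#' @param labels_path Path to a two-column TSV `barcode<TAB>grade` (no
#'   header; exactly two distinct grade strings, mapped to 0/1 in sort
#'   order).
#' @param use_coords `"array"` (default) uses array_row/array_col converted
#'   to planar hex positions with unit nearest-neighbour spacing (Visium
#'   array columns count half-steps, so x = array_col / 2,
#'   y = array_row * sqrt(3) / 2); `"pixel"` uses the full-resolution pixel
#'   centroids unchanged.
#' @param in_tissue_only Keep only spots flagged in-tissue (default `TRUE`).
#' @return An [st_dataset()].
#' @export
read_visium <- function(matrix_dir, positions_path, labels_path,
                        use_coords = c("array", "pixel"),
                        in_tissue_only = TRUE) {
  use_coords <- match.arg(use_coords)
  mtx <- find_one(matrix_dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find_one(matrix_dir, c(
    "features.tsv", "features.tsv.gz",
    "genes.tsv", "genes.tsv.gz"
  ))
  bar <- find_one(matrix_dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readr::read_tsv(feat,
    col_names = FALSE, show_col_types = FALSE,
    progress = FALSE
  )
  barcodes <- readr::read_tsv(bar,
    col_names = FALSE, show_col_types = FALSE,
    progress = FALSE
  )[[1]]
  if (nrow(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
    abort("matrix dimensions do not match features/barcodes files.",
      class = "stgee_format_error"
    )
  }
  gene_ids <- make.unique(features[[1]])
  pos <- read_tissue_positions(positions_path)
  if (in_tissue_only) pos <- pos[pos$in_tissue == 1, , drop = FALSE]
  labels_tab <- readr::read_tsv(labels_path,
    col_names = c("barcode", "grade"),
    show_col_types = FALSE, progress = FALSE
  )
  keep <- Reduce(intersect, list(barcodes, pos$barcode, labels_tab$barcode))
  if (length(keep) == 0) {
    abort("no barcode is shared by the matrix, positions and labels files.",
      class = "stgee_value_error"
    )
  }
  dropped <- length(barcodes) - length(keep)
  if (dropped > 0) {
    inform(sprintf("restricting to %d barcodes shared by all inputs (%d dropped).",
      length(keep), dropped))
  }
  keep <- barcodes[barcodes %in% keep] # preserve matrix column order
  col_idx <- match(keep, barcodes)
  pos <- pos[match(keep, pos$barcode), , drop = FALSE]
  grades <- labels_tab$grade[match(keep, labels_tab$barcode)]
  coords <- if (use_coords == "array") {
    tibble(x = pos$array_col / 2, y = pos$array_row * sqrt(3) / 2)
  } else {
    tibble(x = pos$pxl_col_in_fullres, y = pos$pxl_row_in_fullres)
  }
  st_dataset(
    counts = counts[, col_idx, drop = FALSE], coords = coords,
    labels = grades, gene_ids = gene_ids, spot_ids = keep
  )
}

find_one <- function(dir, names) {
  if (!dir.exists(dir)) {
    abort(sprintf("matrix directory '%s' does not exist.", dir),
      class = "stgee_io_error"
    )
  }
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) {
      return(p)
    }
  }
  abort(sprintf("none of %s found in '%s'.", paste(names, collapse = "/"), dir),
    class = "stgee_io_error"
  )
}

visium_pos_cols <- c(
  "barcode", "in_tissue", "array_row", "array_col",
  "pxl_row_in_fullres", "pxl_col_in_fullres"
)

read_tissue_positions <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("positions file '%s' does not exist.", path),
      class = "stgee_io_error"
    )
  }
  first <- readr::read_lines(path, n_max = 1)
  headered <- grepl("barcode", first, fixed = TRUE)
  pos <- readr::read_csv(path,
    col_names = if (headered) TRUE else visium_pos_cols,
    show_col_types = FALSE, progress = FALSE
  )
  if (!all(visium_pos_cols %in% names(pos))) {
    if (headered || ncol(pos) != 6) {
      abort("unrecognized tissue positions dialect.", class = "stgee_format_error")
    }
  }
  pos[visium_pos_cols]
}

#' Write an `st_dataset` in the Visium MTX + TSV layout
#'
#' Counterpart of [read_visium()], used by the simulator to materialize
#' synthetic datasets as fixtures: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` into `dir`, a headerless v1 `tissue_positions_list.csv`
#' (or headered v2 when `positions_format = "v2"`), and a `labels.tsv`.
#' Array rows/columns are reconstructed from the hex coordinates.
#'
#' @param dataset An [st_dataset()].
#' @param dir Output directory (created if needed).
#' @param positions_format `"v1"` (headerless) or `"v2"` (headered).
#' @return Invisibly, the paths written (named list).
#' @export
write_visium <- function(dataset, dir, positions_format = c("v1", "v2")) {
  positions_format <- match.arg(positions_format)
  stopifnot(inherits(dataset, "st_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(as(Matrix::Matrix(dataset$counts, sparse = TRUE), "generalMatrix"), mtx)
  feat <- file.path(dir, "features.tsv")
  readr::write_tsv(
    tibble(
      id = dataset$gene_ids, name = dataset$gene_ids,
      type = "Gene Expression"
    ),
    feat,
    col_names = FALSE
  )
  bar <- file.path(dir, "barcodes.tsv")
  readr::write_tsv(tibble(dataset$spot_ids), bar, col_names = FALSE)
  arr_row <- as.integer(round(dataset$coords$y / (sqrt(3) / 2)))
  pos_tab <- tibble(
    barcode = dataset$spot_ids, in_tissue = 1L,
    array_row = arr_row,
    array_col = as.integer(round(dataset$coords$x * 2)),
    pxl_row_in_fullres = as.integer(round(dataset$coords$y * 100)),
    pxl_col_in_fullres = as.integer(round(dataset$coords$x * 100))
  )
  pos <- file.path(dir, "tissue_positions_list.csv")
  readr::write_csv(pos_tab, pos, col_names = positions_format == "v2")
  lab <- file.path(dir, "labels.tsv")
  readr::write_tsv(
    tibble(
      barcode = dataset$spot_ids,
      grade = ifelse(dataset$labels == 0L, "GradeA", "GradeB")
    ),
    lab,
    col_names = FALSE
  )
  invisible(list(
    matrix_dir = dir, positions = pos, labels = lab,
    matrix = mtx, features = feat, barcodes = bar
  ))
}
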