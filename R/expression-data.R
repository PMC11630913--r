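#' Construct an expression dataset
#'
#' Bundles a genes x cells matrix of normalized (typically log-scale)
#' expression with per-cell cluster labels and pseudotime. Expression is
#' assumed to be already normalized by the user; no transformation is applied.
#'
#' @param mat numeric matrix, genes x cells, with unique row and column names.
#'   Values must be finite and non-negative.
#' @param cluster character vector of cluster labels, either named by cell id
#'   or aligned with `colnames(mat)`.
#' @param pseudotime numeric vector of finite, non-negative pseudotimes,
#'   named or aligned like `cluster`.
#' @param cluster_levels optional character vector fixing the cluster order;
#'   defaults to order of first appearance in `cluster`.
#' @return an object of class `expression_dataset` with fields `matrix`,
#'   `gene_ids`, `cell_ids`, `cluster_of`, `pseudotime_of`, `clusters`.
#' @export
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ds <- expression_dataset(m, rep(c("A", "B"), each = 2), c(0, 0.1, 0.5, 0.6))
#' ds$clusters
expression_dataset <- function(mat, cluster, pseudotime, cluster_levels = NULL) {
  if (inherits(mat, "Matrix")) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stopf("expression matrix needs gene row names and cell column names")
  }
  if (anyDuplicated(rownames(mat))) stopf("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(mat))) stopf("duplicate cell ids in expression matrix")
  if (any(!is.finite(mat))) stopf("expression matrix contains NA/NaN/Inf values; refusing to coerce")
  if (any(mat < 0)) stopf("expression matrix contains negative values")

  cells <- colnames(mat)
  align <- function(x, what) {
    if (!is.null(names(x))) {
      missing <- setdiff(cells, names(x))
      if (length(missing)) {
        stopf("cells missing %s: %s", what, paste(missing, collapse = ", "))
      }
      x[cells]
    } else {
      if (length(x) != length(cells)) stopf("%s length does not match cell count", what)
      stats::setNames(x, cells)
    }
  }
  cluster <- align(as.character(cluster), "cluster labels")
  pseudotime <- align(as.numeric(pseudotime), "pseudotime")
  if (any(!is.finite(pseudotime))) stopf("pseudotime must be finite and numeric")
  if (any(pseudotime < 0)) stopf("pseudotime must be non-negative")
  if (any(is.na(cluster)) || any(cluster == "")) stopf("every cell needs a cluster label")

  levels <- cluster_levels %||% unique(cluster)
  if (!all(cluster %in% levels)) stopf("cluster labels outside supplied cluster_levels")
  levels <- levels[levels %in% cluster]

  structure(list(
    matrix = mat,
    gene_ids = rownames(mat),
    cell_ids = cells,
    cluster_of = cluster,
    pseudotime_of = pseudotime,
    clusters = levels
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d cells, %d clusters (%s)\n",
              length(x$gene_ids), length(x$cell_ids), length(x$clusters),
              paste(head(x$clusters, 8), collapse = ", ")))
  invisible(x)
}

#' Read an expression dataset from disk
#'
#' Reads a genes x cells matrix (CSV with gene ids in the first column and a
#' cell-id header, or MatrixMarket `.mtx` with `<stem>_genes.txt` /
#' `<stem>_cells.txt` sidecar name files, one id per line) together with a
#' per-cell metadata CSV with columns `cell_id`, `cluster`, `pseudotime`.
#'
#' Cells present in the matrix but absent from the metadata are an error;
#' metadata rows for unknown cells are ignored with a warning. Cluster order
#' everywhere downstream is the order of first appearance in the metadata.
#'
#' @param matrix_path path to the matrix CSV or MTX file.
#' @param meta_path path to the metadata CSV.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, meta_path) {
  if (!file.exists(matrix_path)) stopf("expression matrix file not found: %s", matrix_path)
  if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)

  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", matrix_path, ignore.case = TRUE)
    genes_path <- paste0(stem, "_genes.txt")
    cells_path <- paste0(stem, "_cells.txt")
    if (!file.exists(genes_path) || !file.exists(cells_path)) {
      stopf("MTX sidecar files not found: expected %s and %s", genes_path, cells_path)
    }
    mat <- as.matrix(Matrix::readMM(matrix_path))
    rownames(mat) <- readLines(genes_path)
    colnames(mat) <- readLines(cells_path)
  } else {
    df <- read.csv(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) stopf("duplicate gene ids in %s", matrix_path)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- as.character(df[[1]])
    if (!is.numeric(mat)) stopf("non-numeric expression values in %s", matrix_path)
  }

  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cluster", "pseudotime")
  if (!all(need %in% names(meta))) {
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$cell_id)) stopf("duplicate cell ids in metadata")
  missing <- setdiff(colnames(mat), meta$cell_id)
  if (length(missing)) {
    stopf("cells in matrix missing from metadata: %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(meta$cell_id, colnames(mat))
  if (length(extra)) {
    warnf("ignoring %d metadata rows for cells absent from the matrix", length(extra))
    meta <- meta[meta$cell_id %in% colnames(mat), , drop = FALSE]
  }
  if (!is.numeric(meta$pseudotime)) stopf("non-numeric pseudotime in metadata")

  expression_dataset(
    mat,
    cluster = stats::setNames(as.character(meta$cluster), meta$cell_id),
    pseudotime = stats::setNames(meta$pseudotime, meta$cell_id),
    cluster_levels = unique(as.character(meta$cluster))
  )
}

#' Write an expression dataset to CSV files
#'
#' Companion writer to [read_expression()]: writes the matrix as a gene x cell
#' CSV and the metadata as a `cell_id,cluster,pseudotime` CSV.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,meta_path output paths.
#' @return invisibly, `c(matrix_path, meta_path)`.
#' @export
write_expression <- function(ds, matrix_path, meta_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = ds$gene_ids, ds$matrix, check.names = FALSE)
  write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(cell_id = ds$cell_ids,
                     cluster = unname(ds$cluster_of[ds$cell_ids]),
                     pseudotime = unname(ds$pseudotime_of[ds$cell_ids]))
  # keep cluster first-appearance order stable on round trip
  meta <- meta[order(match(meta$cluster, ds$clusters)), , drop = FALSE]
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, meta_path))
}
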