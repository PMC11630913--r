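#' Average expression per cluster
#'
#' @param ds an [expression_dataset()].
#' @param genes genes to include (subset of the dataset's genes); default all.
#' @return numeric matrix genes x clusters of arithmetic cluster means, with
#'   clusters in the dataset's (metadata first-appearance) order.
#' @export
cluster_means <- function(ds, genes = ds$gene_ids) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing)) stopf("genes not in dataset: %s", paste(missing, collapse = ", "))
  out <- vapply(ds$clusters, function(c) {
    cells <- ds$cluster_of == c
    if (!any(cells)) stopf("cluster '%s' has no cells", c)
    rowMeans(ds$matrix[genes, cells, drop = FALSE])
  }, numeric(length(genes)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(genes),
                                       dimnames = list(genes, ds$clusters))
  rownames(out) <- genes
  out
}

# exact 1-D two-means on a vector: returns 0/1 labels (1 = higher group).
# Exhaustive search over the K-1 sorted split points minimizes total
# within-group sum of squares; ties prefer the larger low group (fewer ONs).
two_means_split <- function(v) {
  K <- length(v)
  ord <- order(v)
  sv <- v[ord]
  ss <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  best_i <- 1L
  best_ss <- Inf
  for (i in seq_len(K - 1)) {
    s <- ss(sv[seq_len(i)]) + ss(sv[(i + 1):K])
    if (s < best_ss - 1e-12 || (abs(s - best_ss) <= 1e-12 && i > best_i)) {
      best_ss <- s
      best_i <- i
    }
  }
  labels <- integer(K)
  labels[ord[(best_i + 1):K]] <- 1L
  labels
}

#' Binarize cluster means into Boolean activity profiles
#'
#' Per gene, an exact 1-D two-means clustering of that gene's cluster means
#' (exhaustive split search, deterministic); clusters in the higher-centroid
#' group get status 1. A gene whose cluster means span less than 1e-6
#' (effectively constant) is set to all zeros, so constant genes never become
#' phantom always-on regulators. The partition is invariant to positive
#' affine scaling of a gene's means.
#'
#' @param cm genes x clusters matrix from [cluster_means()].
#' @return integer 0/1 matrix with the same dimnames.
#' @export
#' @examples
#' binarize(rbind(g1 = c(0, 0, 10), g2 = c(1, 2, 8)))
binarize <- function(cm) {
  if (!is.matrix(cm) || !is.numeric(cm)) stopf("cluster means must be a numeric matrix")
  out <- matrix(0L, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  if (ncol(cm) < 2) return(out)   # single cluster: all off by convention
  for (g in seq_len(nrow(cm))) {
    v <- cm[g, ]
    if (max(v) - min(v) < 1e-6) next
    out[g, ] <- two_means_split(v)
  }
  dup <- duplicated(t(out)) | duplicated(t(out), fromLast = TRUE)
  if (ncol(out) > 1 && any(dup)) {
    warnf("clusters with identical Boolean profiles: %s (indistinct clusters degrade inference)",
          paste(colnames(out)[dup] %||% which(dup), collapse = ", "))
  }
  out
}

#' Write a Boolean profile (or cluster-mean) matrix as CSV
#'
#' @param profiles genes x clusters matrix.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(gene = rownames(profiles), profiles, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Boolean profile matrix written by [write_profiles()]
#'
#' @param path CSV path.
#' @return numeric matrix genes x clusters.
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
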