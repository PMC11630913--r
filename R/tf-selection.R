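#' Parameters for dynamic TF selection
#'
#' @param adj_p_threshold BH-adjusted p-value cutoff for the GAM pseudotime
#'   smooth term (default 0.05).
#' @param min_pct_expressed minimum fraction of cells with positive expression
#'   required in at least one cluster (default 0.1).
#' @param min_logfc minimum log2 fold change between the highest- and
#'   lowest-expressing cluster means, with pseudocount 0.01 (default 2).
#' @param gam_basis_dim spline basis dimension of the pseudotime smooth
#'   (default 5, minimum 3).
#' @return a `selection_params` list.
#' @export
selection_params <- function(adj_p_threshold = 0.05, min_pct_expressed = 0.1,
                             min_logfc = 2, gam_basis_dim = 5) {
  stopifnot(adj_p_threshold > 0, adj_p_threshold < 1,
            min_pct_expressed > 0, min_pct_expressed <= 1,
            min_logfc >= 0, gam_basis_dim >= 3)
  structure(list(adj_p_threshold = adj_p_threshold,
                 min_pct_expressed = min_pct_expressed,
                 min_logfc = min_logfc,
                 gam_basis_dim = as.integer(gam_basis_dim)),
            class = "selection_params")
}

#' GAM smooth-term p-value of expression against pseudotime
#'
#' Fits `expr ~ s(pseudotime, k = basis_dim)` with [mgcv::gam()] and returns
#' the approximate significance of the smooth term. Constant expression (and
#' any degenerate fit) returns p = 1: no dynamic signal rather than a failure.
#' The basis dimension is shrunk automatically when pseudotime has too few
#' distinct values to support it.
#'
#' @param expr numeric vector of one gene's expression across cells (>= 10).
#' @param pt matching pseudotimes.
#' @param basis_dim spline basis dimension (default 5).
#' @return a single p-value in `[0, 1]`.
#' @export
gam_pseudotime_pvalue <- function(expr, pt, basis_dim = 5) {
  expr <- as.numeric(expr); pt <- as.numeric(pt)
  if (length(expr) != length(pt)) stopf("expr and pt lengths differ")
  if (length(expr) < 10) stopf("need at least 10 cells for the GAM fit")
  if (any(!is.finite(expr)) || any(!is.finite(pt))) stopf("non-finite values")
  if (sd(expr) < 1e-12) return(1)
  k <- min(basis_dim, length(unique(pt)) - 1L)
  if (k < 3) return(1)
  fit <- tryCatch(
    mgcv::gam(expr ~ s(pt, k = k), method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) return(1)
  p <- tryCatch(summary(fit)$s.table[1, "p-value"], error = function(e) NA_real_)
  if (!is.finite(p)) return(1)
  min(max(p, 0), 1)
}

#' Select dynamically expressed transcription factors
#'
#' A gene is kept when it passes all three filters:
#' \enumerate{
#'   \item its GAM pseudotime smooth is significant (BH-adjusted p below
#'     `adj_p_threshold`) in at least one trajectory of the state graph,
#'     fitted on the cells of that trajectory's clusters only;
#'   \item at least one cluster expresses it in `min_pct_expressed` of cells
#'     (expression strictly above zero);
#'   \item `log2((max cluster mean + 0.01) / (min cluster mean + 0.01))`
#'     reaches `min_logfc`.
#' }
#' BH adjustment is computed across the tested genes within each trajectory.
#'
#' @param ds an [expression_dataset()].
#' @param sg a `state_graph` over the dataset's clusters.
#' @param tf_list optional candidate gene subset (e.g. a curated TF
#'   catalogue); default: all genes.
#' @param params a [selection_params()].
#' @return character vector of selected genes, in dataset order. An empty
#'   result is an error suggesting threshold relaxation.
#' @export
select_dynamic_tfs <- function(ds, sg, tf_list = NULL,
                               params = selection_params()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(sg, "state_graph"))
  genes <- if (is.null(tf_list)) ds$gene_ids else intersect(ds$gene_ids, tf_list)
  if (!length(genes)) stopf("no candidate genes present in the dataset")
  trajs <- enumerate_trajectories(sg)
  covered <- unique(unlist(trajs))
  if (!all(ds$clusters %in% covered)) {
    warnf("cluster(s) not covered by any trajectory: %s",
          paste(setdiff(ds$clusters, covered), collapse = ", "))
  }

  sig_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (traj in trajs) {
    cells <- ds$cell_ids[ds$cluster_of %in% traj]
    if (length(cells) < 10) next
    pt <- ds$pseudotime_of[cells]
    pv <- vapply(genes, function(g) {
      gam_pseudotime_pvalue(ds$matrix[g, cells], pt, params$gam_basis_dim)
    }, 0)
    adj <- p.adjust(pv, method = "BH")
    sig_any <- sig_any | (adj < params$adj_p_threshold)
  }

  pct_ok <- vapply(genes, function(g) {
    any(vapply(ds$clusters, function(c) {
      mean(ds$matrix[g, ds$cluster_of == c] > 0)
    }, 0) >= params$min_pct_expressed)
  }, TRUE)

  eps <- 0.01
  lfc_ok <- vapply(genes, function(g) {
    m <- vapply(ds$clusters, function(c) mean(ds$matrix[g, ds$cluster_of == c]), 0)
    log2((max(m) + eps) / (min(m) + eps)) >= params$min_logfc
  }, TRUE)

  keep <- genes[sig_any & pct_ok & lfc_ok]
  if (!length(keep)) {
    stopf(paste0("no dynamically expressed genes passed the filters; consider ",
                 "raising adj_p_threshold or lowering min_pct_expressed/min_logfc"))
  }
  keep
}
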