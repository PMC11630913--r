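as_edge_keys <- function(g, signed = FALSE, include_self = FALSE) {
  e <- if (inherits(g, "grn")) g$edges else g
  if (!include_self) e <- e[e$regulator != e$target, , drop = FALSE]
  if (signed) paste(e$regulator, e$target, e$sign) else paste(e$regulator, e$target)
}

#' Edge-recovery metrics of an inferred network against a reference
#'
#' Edges are compared as directed regulator->target pairs (signed triples if
#' `signed = TRUE`); self-edges are excluded unless `include_self = TRUE`
#' (the default matches benchmarks against methods producing unsigned,
#' self-loop-free weighted edges).
#'
#' @param inferred,reference [grn()] objects (or edge data.frames with
#'   columns regulator, target, sign).
#' @param signed compare signs too (default FALSE).
#' @param include_self count self-edges (default FALSE).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (precision/recall are 0 when their denominator is 0; f1 is the harmonic
#'   mean, 0 when both are 0).
#' @export
#' @examples
#' a <- grn(data.frame(regulator = c("A", "B"), target = c("B", "C"), sign = 1))
#' b <- grn(data.frame(regulator = c("A", "A"), target = c("B", "C"), sign = 1))
#' edge_metrics(a, b)$f1   # 0.5
edge_metrics <- function(inferred, reference, signed = FALSE,
                         include_self = FALSE) {
  ik <- unique(as_edge_keys(inferred, signed, include_self))
  rk <- unique(as_edge_keys(reference, signed, include_self))
  tp <- length(intersect(ik, rk))
  fp <- length(setdiff(ik, rk))
  fn <- length(setdiff(rk, ik))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' F1-maximizing threshold for a weighted edge list
#'
#' Sweeps every distinct weight as a cutoff (edges with weight >= cutoff are
#' kept) and returns the cutoff maximizing F1 against the reference network;
#' ties prefer the larger cutoff (sparser network).
#'
#' @param weighted_edges data.frame with columns `regulator`, `target`,
#'   `weight` (finite).
#' @param reference a [grn()] or edge data.frame.
#' @param include_self count self-edges (default FALSE).
#' @return list with `threshold`, `metrics` (as in [edge_metrics()]) and
#'   `sweep` (data.frame of every cutoff tried). An empty edge list returns
#'   zero metrics and `threshold = NA`.
#' @export
max_f1_threshold <- function(weighted_edges, reference, include_self = FALSE) {
  if (!nrow(weighted_edges)) {
    return(list(threshold = NA_real_,
                metrics = list(tp = 0L, fp = 0L, fn = 0L,
                               precision = 0, recall = 0, f1 = 0),
                sweep = data.frame(threshold = numeric(0), f1 = numeric(0))))
  }
  stopifnot(all(c("regulator", "target", "weight") %in% names(weighted_edges)))
  if (any(!is.finite(weighted_edges$weight))) stopf("non-finite edge weights")
  cuts <- sort(unique(weighted_edges$weight), decreasing = TRUE)
  sweep <- data.frame(threshold = cuts, f1 = NA_real_)
  best <- NULL
  for (i in seq_along(cuts)) {
    keep <- weighted_edges[weighted_edges$weight >= cuts[i], , drop = FALSE]
    keep$sign <- 1L
    m <- edge_metrics(keep, reference, signed = FALSE, include_self = include_self)
    sweep$f1[i] <- m$f1
    if (is.null(best) || m$f1 > best$metrics$f1 + 1e-12) {
      best <- list(threshold = cuts[i], metrics = m)   # ties keep earlier (larger) cutoff
    }
  }
  c(best, list(sweep = sweep))
}

#' Terminal-state fidelity of simulated Boolean end states
#'
#' For each terminal cluster, the highest percent agreement between its
#' Boolean activity profile and any simulated terminal state.
#'
#' @param sim_terminals matrix of simulated terminal Boolean states (rows =
#'   states, columns = genes).
#' @param terminal_profiles 0/1 genes x terminal-clusters matrix.
#' @return named numeric vector in `[0, 1]`, one entry per terminal cluster;
#'   all zeros when the simulated set is empty.
#' @export
terminal_state_fidelity <- function(sim_terminals, terminal_profiles) {
  sim_terminals <- as.matrix(sim_terminals)
  genes <- rownames(terminal_profiles)
  out <- stats::setNames(numeric(ncol(terminal_profiles)), colnames(terminal_profiles))
  if (nrow(sim_terminals) == 0) return(out)
  if (!is.null(colnames(sim_terminals))) {
    if (!all(genes %in% colnames(sim_terminals))) {
      stopf("simulated states missing gene(s): %s",
            paste(setdiff(genes, colnames(sim_terminals)), collapse = ", "))
    }
    sim_terminals <- sim_terminals[, genes, drop = FALSE]
  } else if (ncol(sim_terminals) != length(genes)) {
    stopf("gene count mismatch between simulated states and profiles")
  }
  for (tc in colnames(terminal_profiles)) {
    out[tc] <- max(vapply(seq_len(nrow(sim_terminals)), function(i) {
      mean(sim_terminals[i, ] == terminal_profiles[, tc])
    }, 0))
  }
  out
}

#' Per-gene maximum lagged cross-correlation between two traces
#'
#' For each gene, the maximum over integer lags in `[-max_lag, max_lag]` of
#' the Pearson correlation between the overlapping segments of the two
#' series. Series of unequal length are first linearly rescaled (by index
#' interpolation) to the shorter length. Constant overlapping segments
#' contribute correlation 0.
#'
#' @param trace_a,trace_b genes x time matrices with matching row names (or
#'   `sim_trace` objects).
#' @param max_lag maximum lag in steps; default 10% of the series length.
#' @return named numeric vector in `[-1, 1]`, one entry per gene.
#' @export
trace_cross_correlation <- function(trace_a, trace_b, max_lag = NULL) {
  if (inherits(trace_a, "sim_trace")) trace_a <- trace_a$values
  if (inherits(trace_b, "sim_trace")) trace_b <- trace_b$values
  genes <- rownames(trace_a)
  if (is.null(genes) || !identical(sort(genes), sort(rownames(trace_b)))) {
    stopf("traces must share gene (row) names")
  }
  trace_b <- trace_b[genes, , drop = FALSE]
  len <- min(ncol(trace_a), ncol(trace_b))
  rescale <- function(m) {
    if (ncol(m) == len) return(m)
    t(apply(m, 1, function(v) {
      stats::approx(seq_along(v), v, n = len)$y
    }))
  }
  A <- rescale(trace_a); B <- rescale(trace_b)
  if (is.null(max_lag)) max_lag <- floor(0.1 * len)
  if (len <= max_lag + 2) stopf("series too short for max_lag = %d", max_lag)
  safe_cor <- function(x, y) {
    if (sd(x) < 1e-12 || sd(y) < 1e-12) 0 else cor(x, y)
  }
  vapply(genes, function(g) {
    max(vapply(-max_lag:max_lag, function(l) {
      if (l >= 0) {
        safe_cor(A[g, (1 + l):len], B[g, 1:(len - l)])
      } else {
        safe_cor(A[g, 1:(len + l)], B[g, (1 - l):len])
      }
    }, 0))
  }, 0)
}
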