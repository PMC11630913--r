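new_state_graph <- function(nodes, edges, root, terminals) {
  structure(list(nodes = nodes, edges = edges, root = root, terminals = terminals),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("state_graph: %d clusters, %d edges, root '%s', terminals: %s\n",
              length(x$nodes), nrow(x$edges), x$root,
              paste(x$terminals, collapse = ", ")))
  invisible(x)
}

sg_igraph <- function(sg) {
  igraph::graph_from_data_frame(sg$edges, directed = TRUE,
                                vertices = data.frame(name = sg$nodes))
}

cluster_summaries <- function(ds) {
  cl <- ds$clusters
  mean_pt <- vapply(cl, function(c) mean(ds$pseudotime_of[ds$cluster_of == c]), 0)
  mean_expr <- vapply(cl, function(c) {
    rowMeans(ds$matrix[, ds$cluster_of == c, drop = FALSE])
  }, numeric(length(ds$gene_ids)))
  if (is.null(dim(mean_expr))) mean_expr <- matrix(mean_expr, nrow = 1,
                                                   dimnames = list(ds$gene_ids[1], cl))
  list(mean_pt = mean_pt, mean_expr = mean_expr)
}

#' Build a cell-state transition graph from cluster pseudotime and similarity
#'
#' Constructs a tree over the dataset's clusters: the root is the cluster
#' with minimal mean pseudotime (or a user-supplied root), and every other
#' cluster is attached to the already-placed cluster whose mean expression
#' profile it correlates with most strongly (Pearson, over all genes).
#' Clusters are placed in ascending mean-pseudotime order, so a parent always
#' has smaller mean pseudotime than its child (up to ties). Correlation ties
#' are broken by smaller pseudotime gap, then lexicographic label; if a
#' profile has zero variance the similarity falls back to (negative)
#' Euclidean distance.
#'
#' @param ds an [expression_dataset()].
#' @param root optional root cluster label. A root whose mean pseudotime is
#'   not minimal triggers a warning, not an error (pseudotime orderings are
#'   routinely overridden for known biology).
#' @param terminals optional terminal cluster labels; default: the leaves.
#'   A supplied terminal that is not a leaf is an error.
#' @return a `state_graph` with fields `nodes`, `edges` (parent, child),
#'   `root`, `terminals`.
#' @export
build_transition_graph <- function(ds, root = NULL, terminals = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  cs <- cluster_summaries(ds)
  cl <- ds$clusters
  if (is.null(root)) {
    root <- names(which.min(cs$mean_pt))
  } else {
    if (!root %in% cl) stopf("root cluster '%s' not found in dataset", root)
    if (cs$mean_pt[root] > min(cs$mean_pt) + 1e-12) {
      warnf("root cluster '%s' does not have the minimal mean pseudotime", root)
    }
  }
  rest <- setdiff(cl, root)
  rest <- rest[order(cs$mean_pt[rest], rest)]
  placed <- root
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  for (c in rest) {
    cand <- placed[cs$mean_pt[placed] < cs$mean_pt[c] | placed == root]
    if (!length(cand)) cand <- root
    prof_c <- cs$mean_expr[, c]
    sim <- vapply(cand, function(p) {
      prof_p <- cs$mean_expr[, p]
      if (sd(prof_c) < 1e-12 || sd(prof_p) < 1e-12) {
        -sqrt(sum((prof_c - prof_p)^2))      # zero-variance fallback
      } else {
        cor(prof_c, prof_p)
      }
    }, 0)
    gap <- abs(cs$mean_pt[c] - cs$mean_pt[cand])
    best <- cand[order(-sim, gap, cand)][1]
    edges <- rbind(edges, data.frame(parent = best, child = c,
                                     stringsAsFactors = FALSE))
    placed <- c(placed, c)
  }
  leaves <- setdiff(cl, edges$parent)
  if (length(cl) == 1) leaves <- cl
  if (is.null(terminals)) {
    terminals <- leaves
  } else {
    terminals <- as.character(terminals)
    if (!all(terminals %in% cl)) {
      stopf("terminal cluster(s) not in dataset: %s",
            paste(setdiff(terminals, cl), collapse = ", "))
    }
    bad <- setdiff(terminals, leaves)
    if (length(bad)) {
      stopf("supplied terminal(s) are not leaves of the transition graph: %s",
            paste(bad, collapse = ", "))
    }
  }
  new_state_graph(cl, edges, root, sort(terminals))
}

#' Validate a user-supplied cell-state transition graph
#'
#' User graphs may be DAGs (a node may have several parents, which is flagged
#' in a message); cycles are rejected with the offending nodes named. If a
#' dataset is supplied, edges running from a later cell state (by mean
#' pseudotime) to an earlier one raise a warning, since developmental
#' transition graphs should not point backwards in time.
#'
#' @param edges data.frame with columns `parent`, `child`.
#' @param root root cluster label; defaults to the unique in-degree-0 node.
#' @param terminals terminal labels; default leaves. Non-leaf terminals error.
#' @param ds optional [expression_dataset()] for the pseudotime-direction check.
#' @return a `state_graph`.
#' @export
validate_user_graph <- function(edges, root = NULL, terminals = NULL, ds = NULL) {
  if (!is.data.frame(edges) || !all(c("parent", "child") %in% names(edges))) {
    stopf("edges must be a data.frame with columns parent, child")
  }
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$parent, edges$child))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(cyc)) cyc <- edges$parent[edges$parent == edges$child]
    stopf("transition graph contains a cycle involving: %s",
          paste(sort(unique(cyc)), collapse = ", "))
  }
  indeg <- igraph::degree(g, mode = "in")
  if (is.null(root)) {
    r0 <- names(indeg)[indeg == 0]
    if (length(r0) != 1) {
      stopf("cannot determine root: %d nodes with in-degree 0 (%s)",
            length(r0), paste(r0, collapse = ", "))
    }
    root <- r0
  } else {
    if (!root %in% nodes) stopf("root '%s' not among graph nodes", root)
    if (indeg[[root]] != 0) stopf("root '%s' has incoming edges", root)
  }
  reach <- igraph::subcomponent(g, root, mode = "out")
  if (length(reach) != length(nodes)) {
    stopf("node(s) unreachable from root: %s",
          paste(setdiff(nodes, names(reach)), collapse = ", "))
  }
  multi <- names(indeg)[indeg > 1]
  if (length(multi)) {
    message("node(s) with multiple parents (DAG input accepted): ",
            paste(multi, collapse = ", "))
  }
  leaves <- names(igraph::degree(g, mode = "out"))[igraph::degree(g, mode = "out") == 0]
  if (is.null(terminals)) {
    terminals <- leaves
  } else {
    terminals <- as.character(terminals)
    bad <- setdiff(terminals, leaves)
    if (length(bad)) {
      stopf("supplied terminal(s) are not leaves: %s", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(ds)) {
    cs <- cluster_summaries(ds)
    known <- edges$parent %in% names(cs$mean_pt) & edges$child %in% names(cs$mean_pt)
    back <- known & (cs$mean_pt[edges$parent] > cs$mean_pt[edges$child] + 1e-12)
    if (any(back)) {
      warnf("edge(s) from later to earlier mean pseudotime: %s",
            paste(paste(edges$parent[back], edges$child[back], sep = " -> "),
                  collapse = ", "))
    }
  }
  new_state_graph(nodes, edges, root, sort(terminals))
}

#' Enumerate root-to-terminal trajectories of a state graph
#'
#' @param sg a `state_graph`.
#' @return list of character vectors (cluster paths), one per root-to-terminal
#'   path, ordered by terminal label (then by path, for DAGs with several
#'   paths to one terminal). For a single-node graph, the single trivial path.
#' @export
enumerate_trajectories <- function(sg) {
  stopifnot(inherits(sg, "state_graph"))
  if (length(sg$nodes) == 1) return(list(sg$root))
  g <- sg_igraph(sg)
  out <- list()
  for (t in sort(sg$terminals)) {
    if (t == sg$root) { out <- c(out, list(sg$root)); next }
    ps <- igraph::all_simple_paths(g, from = sg$root, to = t, mode = "out")
    ps <- lapply(ps, function(p) igraph::as_ids(p))
    ps <- ps[order(vapply(ps, paste, "", collapse = "|"))]
    out <- c(out, ps)
  }
  out
}

#' Write / read state-graph edge lists
#'
#' Plain `parent,child` CSV edge list; root and terminals travel in the
#' pipeline config rather than the file.
#'
#' @param sg a `state_graph`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_state_graph <- function(sg, path) {
  stopifnot(inherits(sg, "state_graph"))
  write.csv(sg$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
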