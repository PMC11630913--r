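grn_rule_index <- function(g) {
  rt <- rule_table(g)
  list(act = lapply(rt$act, function(i) as.integer(i - 1L)),
       rep = lapply(rt$rep, function(i) as.integer(i - 1L)),
       genes = rt$genes)
}

as_state_vector <- function(g, state) {
  if (!is.null(names(state))) {
    missing <- setdiff(g$genes, names(state))
    if (length(missing)) stopf("state missing gene(s): %s", paste(missing, collapse = ", "))
    state <- state[g$genes]
  } else if (length(state) != length(g$genes)) {
    stopf("state length does not match gene count")
  }
  s <- as.integer(state)
  if (any(!s %in% c(0L, 1L))) stopf("state must be 0/1")
  s
}

#' One asynchronous Boolean run
#'
#' Repeatedly picks one gene uniformly at random and updates it by its
#' repressor-dominant Boolean rule, stopping when the state is a fixed point
#' under all rules (checked every step) or after `max_steps` single-gene
#' updates. A state that is already a fixed point is returned after zero
#' updates.
#'
#' @param g a [grn()] (every gene needs a rule, i.e. >= 1 regulator).
#' @param init named (or gene-ordered) 0/1 initial state.
#' @param max_steps update budget (default 1000).
#' @param seed RNG seed.
#' @return list with `state` (named 0/1 vector) and `converged` (logical).
#' @export
async_boolean_run <- function(g, init, max_steps = 1000, seed = 1) {
  stopifnot(inherits(g, "grn"))
  check_simulable(g)
  ri <- grn_rule_index(g)
  res <- cpp_async_runs(as_state_vector(g, init), ri$act, ri$rep,
                        1L, as.integer(max_steps), seed)
  list(state = stats::setNames(as.integer(res$finals[1, ]), g$genes),
       converged = res$converged[1])
}

#' Find Boolean steady states by repeated asynchronous simulation
#'
#' Runs `n_runs` seeded asynchronous Boolean simulations from `init` and
#' collects the distinct fixed points reached, with reach counts. Runs that
#' exhaust `max_steps` without reaching a fixed point (e.g. trapped in a
#' cyclic attractor) are counted as non-converged. Every reported fixed point
#' is re-verified against all rules.
#'
#' @param g a [grn()].
#' @param init named (or gene-ordered) 0/1 initial state.
#' @param n_runs number of runs (default 10000).
#' @param max_steps single-gene update budget per run (default 1000).
#' @param seed base seed; run r uses `seed + r - 1`.
#' @return an `attractor_set`: list with `fixed_points` (matrix, one row per
#'   distinct fixed point, columns = genes), `reach_count`, `n_runs`,
#'   `n_nonconverged`, `genes`.
#' @export
find_steady_states <- function(g, init, n_runs = 10000, max_steps = 1000,
                               seed = 1) {
  stopifnot(inherits(g, "grn"))
  check_simulable(g)
  ri <- grn_rule_index(g)
  res <- cpp_async_runs(as_state_vector(g, init), ri$act, ri$rep,
                        as.integer(n_runs), as.integer(max_steps), seed)
  conv <- res$converged
  finals <- res$finals[conv, , drop = FALSE]
  if (nrow(finals)) {
    keys <- apply(finals, 1, paste, collapse = "")
    tab <- table(keys)
    uniq <- finals[!duplicated(keys), , drop = FALSE]
    rownames(uniq) <- keys[!duplicated(keys)]
    colnames(uniq) <- g$genes
    uniq <- uniq[order(rownames(uniq)), , drop = FALSE]
    counts <- stats::setNames(as.integer(tab[rownames(uniq)]), rownames(uniq))
    rt <- rule_table(g)
    for (i in seq_len(nrow(uniq))) {
      if (!all(boolean_update(rt, uniq[i, ]) == uniq[i, ])) {
        stopf("internal: reported state is not a fixed point")   # nocov
      }
    }
  } else {
    uniq <- matrix(integer(0), 0, length(g$genes),
                   dimnames = list(NULL, g$genes))
    counts <- integer(0)
  }
  structure(list(fixed_points = uniq, reach_count = counts,
                 n_runs = as.integer(n_runs),
                 n_nonconverged = sum(!conv), genes = g$genes),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("attractor_set: %d distinct fixed point(s) over %d runs (%d non-converged)\n",
              nrow(x$fixed_points), x$n_runs, x$n_nonconverged))
  invisible(x)
}

#' Enumerate all Boolean fixed points by brute force
#'
#' Checks every state in `{0,1}^n` against all rules; the exact oracle the
#' stochastic search is validated against. Refuses networks with more than
#' 20 genes.
#'
#' @param g a [grn()].
#' @return matrix with one row per fixed point (columns = genes), rows sorted
#'   by state string.
#' @export
enumerate_fixed_points <- function(g) {
  stopifnot(inherits(g, "grn"))
  check_simulable(g)
  n <- length(g$genes)
  if (n > 20) stopf("brute-force enumeration limited to 20 genes (got %d)", n)
  S <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  colnames(S) <- g$genes
  rt <- rule_table(g)
  ok <- rep(TRUE, nrow(S))
  for (gi in seq_len(n)) {
    a <- rt$act[[gi]]
    r <- rt$rep[[gi]]
    on <- if (length(a)) rowSums(S[, a, drop = FALSE]) > 0 else TRUE
    off_rep <- if (length(r)) rowSums(S[, r, drop = FALSE]) == 0 else TRUE
    ok <- ok & ((on & off_rep) == (S[, gi] == 1L))
  }
  fp <- S[ok, , drop = FALSE]
  fp <- fp[order(apply(fp, 1, paste, collapse = "")), , drop = FALSE]
  rownames(fp) <- apply(fp, 1, paste, collapse = "")
  fp
}

#' Steady-state similarity between a reference and an inferred network
#'
#' For each reference steady state, the best-matching inferred steady state
#' is found (fraction of genes with equal Boolean status); the per-reference
#' maxima are averaged. An empty inferred set scores 0. When the reference
#' network has *no* steady state (`cyclic_reference = TRUE`), the score is 1
#' if the inferred set is also empty and 0 if the inferred network has at
#' least one steady state.
#'
#' @param reference_states matrix of reference fixed points (rows = states,
#'   columns = genes), e.g. `attractor_set$fixed_points`.
#' @param inferred_states matrix of inferred fixed points over the same genes
#'   in the same order.
#' @param cyclic_reference set TRUE when the reference has no steady state.
#' @return similarity in `[0, 1]`.
#' @export
steady_state_similarity <- function(reference_states, inferred_states,
                                    cyclic_reference = FALSE) {
  reference_states <- as.matrix(reference_states)
  inferred_states <- as.matrix(inferred_states)
  if (cyclic_reference) {
    return(if (nrow(inferred_states) == 0) 1 else 0)
  }
  if (nrow(reference_states) == 0) {
    stopf("empty reference steady-state set; use cyclic_reference = TRUE")
  }
  if (nrow(inferred_states) == 0) return(0)
  if (!is.null(colnames(reference_states)) && !is.null(colnames(inferred_states)) &&
      !identical(colnames(reference_states), colnames(inferred_states))) {
    stopf("gene order differs between reference and inferred states")
  }
  if (ncol(reference_states) != ncol(inferred_states)) {
    stopf("gene count differs between reference and inferred states")
  }
  per_ref <- vapply(seq_len(nrow(reference_states)), function(i) {
    max(vapply(seq_len(nrow(inferred_states)), function(j) {
      mean(reference_states[i, ] == inferred_states[j, ])
    }, 0))
  }, 0)
  mean(per_ref)
}

#' Signed divergence in steady-state counts
#'
#' @param reference_count,inferred_count non-negative integers.
#' @return `inferred_count - reference_count`.
#' @export
steady_state_count_divergence <- function(reference_count, inferred_count) {
  stopifnot(reference_count >= 0, inferred_count >= 0)
  as.integer(inferred_count) - as.integer(reference_count)
}
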