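#' Genetic-algorithm parameters for subnetwork inference
#'
#' @param population_size chromosomes per generation (default 200).
#' @param generations number of generations (default 300).
#' @param mutation_rate per-locus mutation probability; default `NULL` means
#'   `1 / n_candidates`, resolved per target.
#' @param crossover_rate probability that a child is produced by uniform
#'   crossover of its two parents rather than cloning the first (default 0.5).
#' @param tournament_size tournament selection size (default 3).
#' @param elitism number of best-ever chromosomes carried over (default 1).
#' @param ideal_density preferred subnetwork density; the penalty pulls the
#'   regulator count toward `round(ideal_density * n_candidates)` (default 0.4).
#' @param edge_penalty_weight weight of the edge-count penalty (default 0.01).
#' @param seed RNG seed (default 1).
#' @return a `ga_params` list.
#' @export
ga_params <- function(population_size = 200, generations = 300,
                      mutation_rate = NULL, crossover_rate = 0.5,
                      tournament_size = 3, elitism = 1,
                      ideal_density = 0.4, edge_penalty_weight = 0.01,
                      seed = 1) {
  stopifnot(population_size >= 2, generations >= 1,
            ideal_density > 0, ideal_density <= 1,
            edge_penalty_weight >= 0, tournament_size >= 1, elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 ideal_density = ideal_density,
                 edge_penalty_weight = edge_penalty_weight,
                 seed = as.integer(seed)),
            class = "ga_params")
}

#' Evaluate the Boolean rule implied by a signed regulator assignment
#'
#' Repressor-dominant AND-of-OR semantics: the target is ON iff (no activator
#' is assigned OR at least one assigned activator is ON) AND every assigned
#' repressor is OFF. Evaluation cost is linear in the number of regulators.
#'
#' @param assignment named numeric vector of signs over regulators, values
#'   +1 (activator) or -1 (repressor). Zeros are ignored (no regulation);
#'   an assignment with no nonzero entry is an error (every gene needs at
#'   least one regulator).
#' @param state named 0/1 vector giving the activity status of every assigned
#'   regulator.
#' @return 0 or 1.
#' @export
#' @examples
#' boolean_rule_eval(c(A = 1, B = -1), c(A = 1, B = 0))  # 1
#' boolean_rule_eval(c(A = 1, B = -1), c(A = 1, B = 1))  # 0 (repressor wins)
boolean_rule_eval <- function(assignment, state) {
  assignment <- assignment[assignment != 0]
  if (!length(assignment)) stopf("empty assignment: a target needs >= 1 regulator")
  regs <- names(assignment)
  if (is.null(regs) || !all(regs %in% names(state))) {
    stopf("every assigned regulator needs a status in `state`")
  }
  act <- regs[assignment > 0]
  rep_ <- regs[assignment < 0]
  on <- (length(act) == 0L || any(state[act] == 1)) && all(state[rep_] == 0)
  as.integer(on)
}

#' Build the Boolean evaluation set for one target gene
#'
#' One evaluation pair per state-graph edge `(u, v)` -- the parent profile
#' must drive the target to its status in the child -- plus one self-pair per
#' terminal cluster, so terminal states are required to be fixed points. The
#' root deliberately gets no self-pair: the initial state need not be stable.
#'
#' @param profiles 0/1 genes x clusters matrix covering all graph nodes.
#' @param sg a `state_graph`.
#' @param target gene (row of `profiles`).
#' @return an `evaluation_set`: list with `states` (genes x n_pairs source
#'   profiles), `required` (target status per pair) and `target`.
#' @export
build_evaluation_set <- function(profiles, sg, target) {
  stopifnot(inherits(sg, "state_graph"))
  if (!target %in% rownames(profiles)) stopf("target '%s' not in profiles", target)
  if (!all(sg$nodes %in% colnames(profiles))) {
    stopf("profiles missing cluster(s): %s",
          paste(setdiff(sg$nodes, colnames(profiles)), collapse = ", "))
  }
  src <- c(sg$edges$parent, sg$terminals)
  dst <- c(sg$edges$child, sg$terminals)
  states <- profiles[, src, drop = FALSE]
  colnames(states) <- paste(src, dst, sep = "->")
  structure(list(states = states,
                 required = unname(profiles[target, dst]),
                 target = target),
            class = "evaluation_set")
}

# vectorized fitness of a population matrix P (pop x n_candidates, values
# -1/0/+1) against an evaluation set restricted to the candidate rows.
# Returns list(fitness, agreement, nnz).
fitness_population <- function(P, S, y, ideal_nnz, w) {
  A <- (P == 1) + 0
  R <- (P == -1) + 0
  a_on <- A %*% S
  r_on <- R %*% S
  has_act <- rowSums(A) > 0
  pred <- ((!has_act) | (a_on > 0)) & (r_on == 0)
  agree <- rowMeans(pred == matrix(y, nrow(P), length(y), byrow = TRUE))
  nnz <- rowSums(P != 0)
  list(fitness = agree - w * abs(nnz - ideal_nnz), agreement = agree, nnz = nnz)
}

#' Fitness of a signed regulator assignment
#'
#' `agreement - edge_penalty_weight * |nnz - round(ideal_density * n_candidates)|`,
#' where agreement is the fraction of evaluation pairs on which the assignment's
#' Boolean rule reproduces the target's required status. Bounded above by 1.
#'
#' @param assignment named numeric vector over candidate regulators with
#'   values -1, 0, +1.
#' @param es an [build_evaluation_set()] result.
#' @param params a [ga_params()].
#' @param n_candidates size of the candidate set the penalty is scaled to;
#'   default `length(assignment)`.
#' @return list with `fitness`, `agreement`, `n_edges`.
#' @export
subnetwork_fitness <- function(assignment, es, params = ga_params(),
                               n_candidates = length(assignment)) {
  stopifnot(inherits(es, "evaluation_set"))
  regs <- names(assignment)
  if (is.null(regs) || !all(regs %in% rownames(es$states))) {
    stopf("assignment names must be rows of the evaluation profiles")
  }
  P <- matrix(as.numeric(assignment), 1, length(assignment))
  res <- fitness_population(P, es$states[regs, , drop = FALSE], es$required,
                            round(params$ideal_density * n_candidates),
                            params$edge_penalty_weight)
  list(fitness = res$fitness[1], agreement = res$agreement[1], n_edges = res$nnz[1])
}

# deterministic chromosome ordering key: 0 < +1 < -1 per locus in candidate order
chrom_key <- function(ch) paste(match(ch, c(0, 1, -1)), collapse = "")

# TRUE if (f1, c1) beats (f2, c2): higher fitness, then fewer edges, then key
chrom_better <- function(f1, c1, f2, c2) {
  if (f1 > f2 + 1e-12) return(TRUE)
  if (f1 < f2 - 1e-12) return(FALSE)
  n1 <- sum(c1 != 0); n2 <- sum(c2 != 0)
  if (n1 != n2) return(n1 < n2)
  chrom_key(c1) < chrom_key(c2)
}

#' Infer one target's regulators with a genetic algorithm
#'
#' Searches chromosomes in `{-1, 0, +1}^n_candidates` (repression / none /
#' activation per candidate regulator) for the assignment maximizing
#' [subnetwork_fitness()]: tournament selection, uniform crossover, per-locus
#' mutation resampling uniformly among the two other values, elitism, and a
#' repair step that activates one random locus of an empty chromosome. The
#' best-ever chromosome is returned, with deterministic tie-breaking (fewer
#' edges, then lexicographic regulator order); identical seeds and inputs
#' give identical output.
#'
#' @param target target gene.
#' @param candidates candidate regulators (must include `target`; self-edges
#'   are legitimate).
#' @param profiles 0/1 genes x clusters matrix.
#' @param sg a `state_graph`.
#' @param params a [ga_params()].
#' @return a `subnetwork_config`: list with `target`, `assignment` (named
#'   signs, nonzero only), `fitness`, `agreement`, `history` (per-generation
#'   best fitness).
#' @export
infer_subnetwork <- function(target, candidates, profiles, sg,
                             params = ga_params()) {
  if (!length(candidates)) stopf("no candidate regulators")
  if (!target %in% candidates) stopf("candidates must include the target (self-regulation)")
  es <- build_evaluation_set(profiles, sg, target)
  S <- es$states[candidates, , drop = FALSE]
  y <- es$required
  n <- length(candidates)
  pop <- params$population_size
  mrate <- params$mutation_rate %||% (1 / n)
  ideal <- round(params$ideal_density * n)
  w <- params$edge_penalty_weight
  vals <- c(-1L, 0L, 1L)

  with_seed(params$seed, {
    P <- matrix(sample(vals, pop * n, replace = TRUE), pop, n)
    empty <- rowSums(P != 0) == 0
    if (any(empty)) P[cbind(which(empty), sample.int(n, sum(empty), TRUE))] <- 1L

    best <- NULL; best_f <- -Inf; best_a <- 0
    history <- numeric(params$generations)
    for (gen in seq_len(params$generations)) {
      res <- fitness_population(P, S, y, ideal, w)
      top <- which(res$fitness >= max(res$fitness) - 1e-12)
      for (i in top) {
        if (is.null(best) || chrom_better(res$fitness[i], P[i, ], best_f, best)) {
          best <- P[i, ]; best_f <- res$fitness[i]; best_a <- res$agreement[i]
        }
      }
      history[gen] <- best_f
      if (gen == params$generations) break

      n_child <- pop - params$elitism
      t <- params$tournament_size
      sel <- matrix(sample.int(pop, n_child * 2 * t, replace = TRUE), ncol = t)
      fmat <- matrix(res$fitness[sel], ncol = t)
      win <- sel[cbind(seq_len(nrow(sel)), max.col(fmat, ties.method = "first"))]
      p1 <- win[seq_len(n_child)]
      p2 <- win[n_child + seq_len(n_child)]
      child <- P[p1, , drop = FALSE]
      do_cx <- runif(n_child) < params$crossover_rate
      mask <- matrix(runif(n_child * n) < 0.5, n_child, n) & do_cx
      child[mask] <- P[p2, , drop = FALSE][mask]

      mut <- which(matrix(runif(n_child * n), n_child, n) < mrate)
      if (length(mut)) {
        idx <- match(child[mut], vals)
        step <- sample(1:2, length(mut), replace = TRUE)
        child[mut] <- vals[((idx - 1 + step) %% 3) + 1]
      }
      empty <- rowSums(child != 0) == 0
      if (any(empty)) child[cbind(which(empty), sample.int(n, sum(empty), TRUE))] <- 1L

      P <- if (params$elitism > 0) {
        rbind(matrix(rep(best, params$elitism), params$elitism, n, byrow = TRUE), child)
      } else child
    }
    assignment <- stats::setNames(as.numeric(best), candidates)
    structure(list(target = target,
                   assignment = assignment[assignment != 0],
                   fitness = best_f,
                   agreement = best_a,
                   history = history),
              class = "subnetwork_config")
  })
}

#' Exhaustive search over all signed regulator assignments
#'
#' Brute-force oracle for small candidate sets (`3^n` chromosomes, n <= 10):
#' returns the maximum fitness, the deterministic argmax (same tie-break as
#' the GA) and all fitness-optimal assignments.
#'
#' @inheritParams infer_subnetwork
#' @return list with `fitness`, `assignment`, `optima` (matrix of all optimal
#'   chromosomes over candidates).
#' @export
exhaustive_subnetwork_search <- function(target, candidates, profiles, sg,
                                         params = ga_params()) {
  n <- length(candidates)
  if (n > 10) stopf("exhaustive search limited to 10 candidates")
  es <- build_evaluation_set(profiles, sg, target)
  S <- es$states[candidates, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n)))
  colnames(grid) <- candidates
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  res <- fitness_population(grid, S, es$required,
                            round(params$ideal_density * n),
                            params$edge_penalty_weight)
  fmax <- max(res$fitness)
  opt <- grid[res$fitness >= fmax - 1e-12, , drop = FALSE]
  keys <- apply(opt, 1, chrom_key)
  nnz <- rowSums(opt != 0)
  pick <- order(nnz, keys)[1]
  a <- stats::setNames(as.numeric(opt[pick, ]), candidates)
  list(fitness = fmax, assignment = a[a != 0], optima = opt)
}

#' Compile per-target subnetwork configs into one GRN
#'
#' Takes the union of all inferred edges. Any gene left without a regulator
#' receives a self-activation edge (reported via message), so the compiled
#' network always satisfies the simulation constraint that every gene has at
#' least one regulator.
#'
#' @param configs list of `subnetwork_config` objects, one per target gene.
#' @return a [grn()].
#' @export
compile_grn <- function(configs) {
  targets <- vapply(configs, function(x) x$target, "")
  if (anyDuplicated(targets)) {
    stopf("duplicate target(s): %s", paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  rows <- lapply(configs, function(cfg) {
    if (!length(cfg$assignment)) return(NULL)
    data.frame(regulator = names(cfg$assignment), target = cfg$target,
               sign = as.integer(sign(cfg$assignment)), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  orphan <- setdiff(targets, edges$target)
  if (length(orphan)) {
    message("adding self-activation to regulator-free gene(s): ",
            paste(orphan, collapse = ", "))
    edges <- rbind(edges, data.frame(regulator = orphan, target = orphan,
                                     sign = 1L, stringsAsFactors = FALSE))
  }
  g <- grn(edges, genes = union(targets, unique(edges$regulator)))
  check_simulable_targets(g, targets)
  g
}

check_simulable_targets <- function(g, targets) {
  missing <- setdiff(targets, unique(g$edges$target))
  if (length(missing)) stopf("internal: unregulated gene(s) after compile: %s",
                             paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Infer a full GRN: one GA search per target gene
#'
#' Runs [infer_subnetwork()] for every gene (all selected genes, self
#' included, are candidate regulators of every target) with per-target seeds
#' `params$seed + target index`, then compiles with [compile_grn()].
#'
#' @param profiles 0/1 genes x clusters matrix of the selected genes.
#' @param sg a `state_graph`.
#' @param params a [ga_params()].
#' @param candidates candidate/target gene set; default all profile rows.
#' @return a [grn()] with attribute `configs` (the per-target
#'   `subnetwork_config` list, including fitness histories).
#' @export
infer_grn <- function(profiles, sg, params = ga_params(),
                      candidates = rownames(profiles)) {
  configs <- lapply(seq_along(candidates), function(i) {
    p <- params
    p$seed <- params$seed + i
    infer_subnetwork(candidates[i], candidates, profiles, sg, p)
  })
  g <- compile_grn(configs)
  attr(g, "configs") <- configs
  g
}
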