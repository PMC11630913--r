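#' Simulation parameters
#'
#' Defaults give a bistable-friendly regime: saturated ON level `m/gamma = 2`,
#' activity threshold `theta = m/(2*gamma) = 1` halfway between OFF and ON,
#' and a soft-heaviside steep enough (`k = 10`) that Boolean logic is
#' recovered at saturated expression.
#'
#' @param m maximal production rate (default 2).
#' @param gamma first-order decay rate (default 1).
#' @param k soft-heaviside steepness (default 10).
#' @param theta activity threshold on expression (default `m / (2 * gamma)`).
#' @param sigma additive noise amplitude (default 0.3).
#' @param dt Euler-Maruyama step size (default 0.01; requires `dt * gamma < 1`).
#' @param n_steps steps per run (default 1800).
#' @param n_runs number of stochastic runs (default 200).
#' @param seed base seed; run `r` uses `seed + r - 1` (default 1).
#' @return a `sim_params` list.
#' @export
sim_params <- function(m = 2, gamma = 1, k = 10, theta = m / (2 * gamma),
                       sigma = 0.3, dt = 0.01, n_steps = 1800, n_runs = 200,
                       seed = 1) {
  stopifnot(m > 0, gamma > 0, k > 0, dt > 0, sigma >= 0,
            n_steps >= 1, n_runs >= 1)
  if (dt * gamma >= 1) stopf("dt * gamma must be < 1 for stability")
  if (theta <= 0 || theta >= m / gamma) stopf("theta must lie in (0, m/gamma)")
  structure(list(m = m, gamma = gamma, k = k, theta = theta, sigma = sigma,
                 dt = dt, n_steps = as.integer(n_steps),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "sim_params")
}

#' Describe an in-silico perturbation
#'
#' A knockout clamps the gene's production term to 0 *and* its expression to
#' 0 inside the window (so downstream logic sees it as off, bit-exactly);
#' an overexpression clamps the production term to its maximum.
#'
#' @param gene gene to perturb.
#' @param kind `"knockout"` or `"overexpression"`.
#' @param start_step first step of the clamp window (default 0 = from the
#'   initial state onward).
#' @param end_step last step of the window (default `NULL` = end of run).
#' @return a `perturbation` list.
#' @export
perturbation <- function(gene, kind = c("knockout", "overexpression"),
                         start_step = 0, end_step = NULL) {
  kind <- match.arg(kind)
  stopifnot(start_step >= 0, is.null(end_step) || end_step > start_step)
  structure(list(gene = gene, kind = kind,
                 start_step = as.integer(start_step),
                 end_step = if (is.null(end_step)) NULL else as.integer(end_step)),
            class = "perturbation")
}

#' Soft heaviside (logistic) activity of an expression level
#'
#' `1 / (1 + exp(-k * (x - theta)))`: monotone increasing, 0.5 at `x = theta`,
#' approaching a step function as `k` grows.
#'
#' @param x expression value(s), >= 0.
#' @param k steepness.
#' @param theta threshold.
#' @return values in (0, 1).
#' @export
#' @examples
#' soft_heaviside(1, k = 10, theta = 1)   # 0.5
soft_heaviside <- function(x, k, theta) {
  1 / (1 + exp(-k * (x - theta)))
}

#' Fuzzy production activity of one gene
#'
#' Goedel fuzzy semantics of the repressor-dominant Boolean rule:
#' `min(max over activators of H(x), 1 - max over repressors of H(x))`,
#' with the activator term 1 when no activator is assigned. Linear cost in
#' the number of regulators; at saturated inputs and steep `k` it reproduces
#' [boolean_rule_eval()] on the binarized state.
#'
#' @param g a [grn()].
#' @param gene target gene (must have >= 1 regulator).
#' @param x named expression vector over the network genes.
#' @param params a [sim_params()].
#' @return production activity in `[0, 1]`.
#' @export
production_activity <- function(g, gene, x, params = sim_params()) {
  stopifnot(inherits(g, "grn"))
  e <- g$edges[g$edges$target == gene, , drop = FALSE]
  if (!nrow(e)) stopf("gene '%s' has no regulator", gene)
  H <- soft_heaviside(x, params$k, params$theta)
  act <- e$regulator[e$sign == 1]
  rep_ <- e$regulator[e$sign == -1]
  a <- if (length(act)) max(H[act]) else 1
  r <- if (length(rep_)) 1 - max(H[rep_]) else 1
  min(a, r)
}

pert_active <- function(p, t, n_steps) {
  end <- p$end_step %||% n_steps
  t > p$start_step && t <= end
}

#' Simulate a GRN as a stochastic continuous system
#'
#' Euler-Maruyama integration of
#' `x_g <- max(0, x_g + (m * B_g(x) - gamma * x_g) * dt + sigma * sqrt(dt) * xi)`
#' where `B_g` is the gene's fuzzy Boolean production activity
#' ([production_activity()]) and `xi` is standard normal, drawn independently
#' per gene, step and run. Genes start at `m/gamma` (status 1) or 0
#' (status 0). Run `r` draws its noise from its own stream seeded
#' `seed + r - 1`, so runs are reproducible and order-independent.
#' Knockouts clamp production to 0 and the state to 0 (applied after the
#' update, hence bit-exact); overexpression clamps production to 1.
#'
#' @param g a [grn()]; every gene must have at least one regulator.
#' @param init_status named 0/1 vector over the network genes (e.g. a column
#'   of a Boolean profile matrix).
#' @param params a [sim_params()].
#' @param perturbations list of [perturbation()] objects.
#' @return list of `n_runs` objects of class `sim_trace`, each with `values`
#'   (genes x `n_steps + 1`, columns named by step `0..n_steps`), `dt`,
#'   `run_id` and `perturbations`.
#' @export
simulate_grn <- function(g, init_status, params = sim_params(),
                         perturbations = list()) {
  stopifnot(inherits(g, "grn"))
  check_simulable(g)
  if (inherits(perturbations, "perturbation")) perturbations <- list(perturbations)
  genes <- g$genes
  if (is.null(names(init_status)) && length(init_status) == length(genes)) {
    names(init_status) <- genes
  }
  if (!all(genes %in% names(init_status))) {
    stopf("init_status missing gene(s): %s",
          paste(setdiff(genes, names(init_status)), collapse = ", "))
  }
  for (p in perturbations) {
    if (!inherits(p, "perturbation")) stopf("perturbations must be perturbation() objects")
    if (!p$gene %in% genes) stopf("perturbed gene '%s' not in network", p$gene)
    end <- p$end_step %||% params$n_steps
    if (end > params$n_steps) stopf("perturbation window exceeds n_steps")
  }

  rt <- rule_table(g)
  n <- length(genes)
  n_steps <- params$n_steps
  n_runs <- params$n_runs
  m <- params$m; gamma <- params$gamma; k <- params$k
  theta <- params$theta; sigma <- params$sigma; dt <- params$dt

  noise <- array(0, c(n, n_steps, n_runs))
  with_seed(params$seed, {
    for (r in seq_len(n_runs)) {
      set.seed(params$seed + r - 1L)
      noise[, , r] <- matrix(rnorm(n * n_steps), n, n_steps)
    }
  })

  X <- matrix(ifelse(init_status[genes] > 0.5, m / gamma, 0), n, n_runs)
  for (p in perturbations) {       # clamp the recorded initial state too
    if (p$kind == "knockout" && p$start_step == 0L) X[match(p$gene, genes), ] <- 0
  }
  values <- array(0, c(n, n_steps + 1L, n_runs))
  values[, 1L, ] <- X

  B <- matrix(0, n, n_runs)
  sn <- sigma * sqrt(dt)
  for (t in seq_len(n_steps)) {
    H <- 1 / (1 + exp(-k * (X - theta)))
    for (gi in seq_len(n)) {
      acts <- rt$act[[gi]]
      reps <- rt$rep[[gi]]
      a <- if (!length(acts)) 1
           else if (length(acts) == 1L) H[acts, ]
           else do.call(pmax, lapply(acts, function(i) H[i, ]))
      r <- if (!length(reps)) 1
           else if (length(reps) == 1L) 1 - H[reps, ]
           else 1 - do.call(pmax, lapply(reps, function(i) H[i, ]))
      B[gi, ] <- pmin(a, r)
    }
    for (p in perturbations) {
      if (pert_active(p, t, n_steps)) {
        B[match(p$gene, genes), ] <- if (p$kind == "knockout") 0 else 1
      }
    }
    X <- pmax(X + (m * B - gamma * X) * dt + sn * noise[, t, ], 0)
    for (p in perturbations) {
      if (p$kind == "knockout" && pert_active(p, t, n_steps)) {
        X[match(p$gene, genes), ] <- 0
      }
    }
    values[, t + 1L, ] <- X
  }

  lapply(seq_len(n_runs), function(r) {
    v <- values[, , r, drop = FALSE]
    dim(v) <- c(n, n_steps + 1L)
    dimnames(v) <- list(genes, 0:n_steps)
    structure(list(values = v, dt = dt, run_id = r,
                   perturbations = perturbations),
              class = "sim_trace")
  })
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("sim_trace: run %d, %d genes x %d timesteps (dt = %g)%s\n",
              x$run_id, nrow(x$values), ncol(x$values), x$dt,
              if (length(x$perturbations)) {
                paste0("; perturbations: ",
                       paste(vapply(x$perturbations,
                                    function(p) paste(p$kind, p$gene), ""),
                             collapse = ", "))
              } else ""))
  invisible(x)
}

#' Classify simulated states against cluster Boolean profiles
#'
#' Expression is binarized at the activity threshold (`x >= theta` is ON).
#' Every sampled step is labelled with the cluster whose Boolean profile has
#' minimal Hamming distance (ties go to the earliest cluster in profile
#' column order, i.e. state-graph order). The run's final state is labelled
#' by *exact* match against the terminal clusters' profiles and `"other"`
#' otherwise.
#'
#' @param trace a `sim_trace`.
#' @param profiles 0/1 genes x clusters matrix whose column order follows the
#'   state graph.
#' @param terminals terminal cluster labels (columns of `profiles`).
#' @param params the [sim_params()] used for the simulation (for `theta`).
#' @param subsample_every label every k-th step (default 1).
#' @return list with `steps` (sampled step indices), `labels` (per sampled
#'   step) and `terminal` (label of the final state or `"other"`).
#' @export
classify_states <- function(trace, profiles, terminals, params = sim_params(),
                            subsample_every = 1) {
  stopifnot(inherits(trace, "sim_trace"), subsample_every >= 1)
  genes <- rownames(trace$values)
  if (!all(genes %in% rownames(profiles))) {
    stopf("profiles missing gene(s): %s",
          paste(setdiff(genes, rownames(profiles)), collapse = ", "))
  }
  if (!all(terminals %in% colnames(profiles))) {
    stopf("terminal(s) not in profiles: %s",
          paste(setdiff(terminals, colnames(profiles)), collapse = ", "))
  }
  P <- profiles[genes, , drop = FALSE]
  n_steps <- ncol(trace$values) - 1L
  steps <- seq(0L, n_steps, by = as.integer(subsample_every))
  bin <- (trace$values[, steps + 1L, drop = FALSE] >= params$theta) + 0L
  labels <- vapply(seq_along(steps), function(j) {
    d <- colSums(P != bin[, j])
    colnames(P)[which.min(d)]       # which.min: earliest column on ties
  }, "")
  final <- (trace$values[, n_steps + 1L] >= params$theta) + 0L
  term <- "other"
  for (tc in terminals) {
    if (all(P[, tc] == final)) { term <- tc; break }
  }
  list(steps = steps, labels = labels, terminal = term)
}
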