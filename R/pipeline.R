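#' Read a pipeline configuration file
#'
#' YAML with sections `paths` (expression, metadata, optional state_graph /
#' grn / tf_list, output_dir), optional `root`, `terminals`, `init_cluster`,
#' `selection`, `ga`, `sim`, `perturbations` (list of gene/kind/start_step/
#' end_step), `subsample_every` and a global `seed`. Every numeric default
#' matches the corresponding module default and is overridable.
#'
#' @param path YAML config path (or an already-parsed list, returned as is).
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (is.list(path)) return(path)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

log_line <- function(log_path, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
}

apply_params <- function(constructor, overrides) {
  if (is.null(overrides)) return(constructor())
  do.call(constructor, overrides)
}

prepare_output <- function(config) {
  out <- config$paths$output_dir %||% stopf("config needs paths$output_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "log.txt")
  if (file.exists(log_path)) file.remove(log_path)
  list(dir = out, log = log_path)
}

load_dataset <- function(config) {
  p <- config$paths
  if (is.null(p$expression) || is.null(p$metadata)) {
    stopf("config needs paths$expression and paths$metadata")
  }
  read_expression(p$expression, p$metadata)
}

config_perturbations <- function(config) {
  lapply(config$perturbations %||% list(), function(p) {
    perturbation(p$gene, p$kind, start_step = p$start_step %||% 0,
                 end_step = p$end_step)
  })
}

#' Run the inference pipeline
#'
#' Dataset -> state graph (built or validated) -> dynamic TF selection ->
#' Boolean profiles -> per-target GA -> compiled GRN. Writes
#' `state_graph.csv`, `selected_tfs.csv`, `cluster_means.csv`,
#' `boolean_profiles.csv`, `fitness_log.csv`, `grn.csv` and a plain-text
#' `log.txt` recording every default used. Reruns with the same seed produce
#' byte-identical outputs.
#'
#' @param config config list or YAML path (see [read_pipeline_config()]).
#' @return invisibly, a list with the in-memory artifacts.
#' @export
run_infer <- function(config) {
  config <- read_pipeline_config(config)
  out <- prepare_output(config)
  seed <- config$seed %||% 1
  log_line(out$log, "stage=infer seed=%d", as.integer(seed))

  ds <- load_dataset(config)
  log_line(out$log, "dataset: %d genes x %d cells, %d clusters",
           length(ds$gene_ids), length(ds$cell_ids), length(ds$clusters))

  if (!is.null(config$paths$state_graph)) {
    edges <- read.csv(config$paths$state_graph, stringsAsFactors = FALSE)
    sg <- validate_user_graph(edges, root = config$root,
                              terminals = config$terminals, ds = ds)
    log_line(out$log, "state graph: user-supplied (%s)", config$paths$state_graph)
  } else {
    sg <- build_transition_graph(ds, root = config$root,
                                 terminals = config$terminals)
    log_line(out$log, "state graph: auto-built (pearson parent choice)")
  }
  log_line(out$log, "root=%s terminals=%s", sg$root,
           paste(sg$terminals, collapse = ","))
  write_state_graph(sg, file.path(out$dir, "state_graph.csv"))

  sel_params <- apply_params(selection_params, config$selection)
  tf_list <- if (!is.null(config$paths$tf_list)) {
    read.csv(config$paths$tf_list, stringsAsFactors = FALSE)[[1]]
  } else NULL
  sel <- select_dynamic_tfs(ds, sg, tf_list = tf_list, params = sel_params)
  log_line(out$log, "selection: adj_p<%g pct>=%g logfc>=%g k=%d -> %d genes",
           sel_params$adj_p_threshold, sel_params$min_pct_expressed,
           sel_params$min_logfc, sel_params$gam_basis_dim, length(sel))
  write.csv(data.frame(gene = sel), file.path(out$dir, "selected_tfs.csv"),
            row.names = FALSE, quote = FALSE)

  cm <- cluster_means(ds, sel)
  profiles <- binarize(cm)
  write_profiles(cm, file.path(out$dir, "cluster_means.csv"))
  write_profiles(profiles, file.path(out$dir, "boolean_profiles.csv"))

  ga <- apply_params(ga_params, config$ga)
  ga$seed <- stage_seed(seed, "inference")
  log_line(out$log,
           "ga: pop=%d gens=%d ideal_density=%g penalty=%g stage_seed=%d",
           ga$population_size, ga$generations, ga$ideal_density,
           ga$edge_penalty_weight, ga$seed)
  g <- infer_grn(profiles, sg, ga)
  write_grn(g, file.path(out$dir, "grn.csv"))

  configs <- attr(g, "configs")
  fit_log <- do.call(rbind, lapply(configs, function(cfg) {
    data.frame(target = cfg$target, generation = seq_along(cfg$history),
               best_fitness = cfg$history)
  }))
  write.csv(fit_log, file.path(out$dir, "fitness_log.csv"),
            row.names = FALSE, quote = FALSE)
  log_line(out$log, "grn: %d genes, %d edges", length(g$genes), nrow(g$edges))

  invisible(list(dataset = ds, state_graph = sg, selected = sel,
                 profiles = profiles, grn = g, output_dir = out$dir))
}

#' Run the simulation pipeline
#'
#' Simulates a GRN (inferred or user-supplied) from the Boolean profile of an
#' initial cluster; writes subsampled per-run traces, a combined long table,
#' a synthetic-cell table, a per-run terminal-state label table
#' (`terminal_states.csv`) and terminal-state proportions
#' (`terminal_proportions.csv`).
#'
#' @param config config list or YAML path. Needs `paths$grn` and
#'   `paths$profiles` (e.g. the `grn.csv` / `boolean_profiles.csv` of a
#'   previous [run_infer()]), `init_cluster`, and `terminals` (defaults to
#'   all non-initial profile columns).
#' @return invisibly, list with `traces`, `labels`, `proportions`.
#' @export
run_simulate <- function(config) {
  config <- read_pipeline_config(config)
  out <- prepare_output(config)
  seed <- config$seed %||% 1

  if (is.null(config$paths$grn)) stopf("config needs paths$grn")
  if (is.null(config$paths$profiles)) stopf("config needs paths$profiles")
  g <- read_grn(config$paths$grn)
  check_simulable(g)
  profiles <- read_profiles(config$paths$profiles)
  init_cluster <- config$init_cluster %||% colnames(profiles)[1]
  if (!init_cluster %in% colnames(profiles)) {
    stopf("init_cluster '%s' not a profile column", init_cluster)
  }
  terminals <- config$terminals %||% setdiff(colnames(profiles), init_cluster)

  sp <- apply_params(sim_params, config$sim)
  sp$seed <- stage_seed(seed, "simulation")
  perts <- config_perturbations(config)
  log_line(out$log,
           "stage=simulate seed=%d stage_seed=%d runs=%d steps=%d dt=%g sigma=%g perturbations=%d",
           as.integer(seed), sp$seed, sp$n_runs, sp$n_steps, sp$dt, sp$sigma,
           length(perts))

  init <- profiles[g$genes, init_cluster]
  traces <- simulate_grn(g, init, sp, perts)

  stride <- config$subsample_every %||% 50
  write_traces(traces, file.path(out$dir, "traces"), subsample_every = stride)
  write.csv(synthetic_cells(traces, subsample_every = stride),
            file.path(out$dir, "synthetic_cells.csv"),
            row.names = FALSE, quote = FALSE)

  labels <- vapply(traces, function(tr) {
    classify_states(tr, profiles, terminals, sp, subsample_every = stride)$terminal
  }, "")
  lab_df <- data.frame(run_id = vapply(traces, function(tr) tr$run_id, 0L),
                       terminal = labels)
  write.csv(lab_df, file.path(out$dir, "terminal_states.csv"),
            row.names = FALSE, quote = FALSE)

  lv <- c(terminals, "other")
  prop <- table(factor(labels, levels = lv)) / length(labels)
  prop_df <- data.frame(terminal = names(prop),
                        proportion = as.numeric(prop))
  write.csv(prop_df, file.path(out$dir, "terminal_proportions.csv"),
            row.names = FALSE, quote = FALSE)
  log_line(out$log, "terminal proportions: %s",
           paste(sprintf("%s=%.3f", prop_df$terminal, prop_df$proportion),
                 collapse = " "))

  invisible(list(traces = traces, labels = lab_df, proportions = prop_df))
}

#' Run the evaluation pipeline
#'
#' Compares an inferred network (concrete or weighted edge list) with a
#' reference network: edge metrics (with an F1-maximizing threshold sweep for
#' weighted input), plus steady-state count divergence and similarity when an
#' initial state is available. Gene-namespace mismatches are reported with
#' the symmetric difference.
#'
#' @param config config list or YAML path. Needs `paths$reference` and either
#'   `paths$inferred` (GRN CSV) or `paths$weighted` (CSV with columns
#'   regulator, target, weight). Optional `init_cluster` + `paths$profiles`
#'   enable the steady-state comparison.
#' @return invisibly, list of metrics.
#' @export
run_evaluate <- function(config) {
  config <- read_pipeline_config(config)
  out <- prepare_output(config)
  reference <- read_grn(config$paths$reference %||% stopf("config needs paths$reference"))

  res <- list()
  if (!is.null(config$paths$weighted)) {
    we <- read.csv(config$paths$weighted, stringsAsFactors = FALSE)
    sweep <- max_f1_threshold(we, reference)
    res$threshold <- sweep$threshold
    res$metrics <- sweep$metrics
    keep <- we[we$weight >= sweep$threshold, , drop = FALSE]
    keep$sign <- 1L
    inferred <- grn(keep)
    log_line(out$log, "weighted input: threshold=%g", sweep$threshold)
  } else if (!is.null(config$paths$inferred)) {
    inferred <- read_grn(config$paths$inferred)
    res$metrics <- edge_metrics(inferred, reference,
                                signed = isTRUE(config$signed),
                                include_self = isTRUE(config$include_self))
  } else {
    stopf("config needs paths$inferred or paths$weighted")
  }
  mismatch <- c(setdiff(inferred$genes, reference$genes),
                setdiff(reference$genes, inferred$genes))
  if (length(mismatch)) {
    log_line(out$log, "gene namespace symmetric difference: %s",
             paste(mismatch, collapse = ","))
  }
  m <- res$metrics
  write.csv(data.frame(tp = m$tp, fp = m$fp, fn = m$fn,
                       precision = m$precision, recall = m$recall, f1 = m$f1,
                       threshold = res$threshold %||% NA),
            file.path(out$dir, "edge_metrics.csv"),
            row.names = FALSE, quote = FALSE)

  if (!is.null(config$paths$profiles) && !is.null(config$init_cluster)) {
    profiles <- read_profiles(config$paths$profiles)
    seed <- stage_seed(config$seed %||% 1, "evaluation")
    shared <- intersect(reference$genes, inferred$genes)
    init_for <- function(g) {       # genes absent from the profiles start OFF
      init <- stats::setNames(rep(0, length(g$genes)), g$genes)
      have <- intersect(g$genes, rownames(profiles))
      init[have] <- profiles[have, config$init_cluster]
      init
    }
    ss_ref <- find_steady_states(reference, init_for(reference), seed = seed)
    ss_inf <- find_steady_states(inferred, init_for(inferred), seed = seed + 1)
    res$divergence <- steady_state_count_divergence(nrow(ss_ref$fixed_points),
                                                    nrow(ss_inf$fixed_points))
    cyc <- nrow(ss_ref$fixed_points) == 0
    res$similarity <- steady_state_similarity(
      ss_ref$fixed_points[, shared, drop = FALSE],
      ss_inf$fixed_points[, shared, drop = FALSE],
      cyclic_reference = cyc)
    write.csv(data.frame(reference_states = nrow(ss_ref$fixed_points),
                         inferred_states = nrow(ss_inf$fixed_points),
                         divergence = res$divergence,
                         similarity = res$similarity),
              file.path(out$dir, "steady_states.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(res)
}

#' Emit a complete toy fixture directory
#'
#' Generates a planted random network, its Boolean trajectory, and a noisy
#' synthetic dataset, and writes `expression.csv`, `metadata.csv`,
#' `truth_grn.csv`, `truth_profiles.csv` into the output directory -- ready
#' to be fed to [run_infer()].
#'
#' @param config config list or YAML path with `paths$output_dir` and an
#'   optional `fixtures` section (n_nodes, density, cells_per_cluster,
#'   noise_sd, dropout).
#' @return invisibly, list with the generated objects and file paths.
#' @export
run_fixtures <- function(config) {
  config <- read_pipeline_config(config)
  out <- prepare_output(config)
  seed <- stage_seed(config$seed %||% 1, "fixtures")
  fx <- config$fixtures %||% list()
  n_nodes <- fx$n_nodes %||% 5
  density <- fx$density %||% 0.2
  gen <- planted_instance(n_nodes, density, seed = seed)
  if (is.null(gen)) stopf("no planted instance with a stable terminal state found")
  net <- gen$grn
  traj <- gen$trajectory
  profiles <- t(traj)
  colnames(profiles) <- paste0("S", seq_len(ncol(profiles)))
  ds <- expression_from_profiles(profiles,
                                 cells_per_cluster = fx$cells_per_cluster %||% 100,
                                 noise_sd = fx$noise_sd %||% 0.5,
                                 dropout = fx$dropout %||% 0,
                                 seed = seed + 1)
  write_expression(ds, file.path(out$dir, "expression.csv"),
                   file.path(out$dir, "metadata.csv"))
  write_grn(net, file.path(out$dir, "truth_grn.csv"))
  write_profiles(profiles, file.path(out$dir, "truth_profiles.csv"))
  log_line(out$log, "fixtures: n_nodes=%d density=%g states=%d seed=%d",
           n_nodes, density, ncol(profiles), seed)
  invisible(list(grn = net, profiles = profiles, dataset = ds,
                 output_dir = out$dir))
}
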