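#' Write one simulation trace to CSV
#'
#' Writes genes as rows and sampled timesteps as columns (labelled by step
#' index: `0, subsample_every, 2*subsample_every, ...`). A YAML sidecar
#' `<path>.meta.yaml` records `dt`, `run_id` and the perturbations.
#'
#' @param trace a `sim_trace` from [simulate_grn()].
#' @param path output CSV path.
#' @param subsample_every keep every k-th step (default 1 = all steps).
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path, subsample_every = 1) {
  stopifnot(inherits(trace, "sim_trace"), subsample_every >= 1)
  n_steps <- ncol(trace$values) - 1L
  steps <- seq(0L, n_steps, by = as.integer(subsample_every))
  v <- trace$values[, steps + 1L, drop = FALSE]
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  colnames(df) <- c("gene", steps)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(dt = trace$dt, run_id = trace$run_id,
               perturbations = lapply(trace$perturbations, function(p) {
                 list(gene = p$gene, kind = p$kind,
                      start_step = p$start_step,
                      end_step = p$end_step %||% n_steps)
               }))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write a set of runs: per-run CSVs plus one combined long-format table
#'
#' @param traces list of `sim_trace` objects.
#' @param dir output directory (created if needed).
#' @param subsample_every keep every k-th step (default 1).
#' @return invisibly, the path of the combined long table
#'   (`<dir>/traces_long.csv`, columns run_id, step, gene, value).
#' @export
write_traces <- function(traces, dir, subsample_every = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    write_trace(tr, file.path(dir, sprintf("trace_run%03d.csv", tr$run_id)),
                subsample_every)
    n_steps <- ncol(tr$values) - 1L
    steps <- seq(0L, n_steps, by = as.integer(subsample_every))
    v <- tr$values[, steps + 1L, drop = FALSE]
    long[[i]] <- data.frame(run_id = tr$run_id,
                            step = rep(steps, each = nrow(v)),
                            gene = rep(rownames(v), length(steps)),
                            value = as.vector(v))
  }
  out <- file.path(dir, "traces_long.csv")
  write.csv(do.call(rbind, long), out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Synthetic-cell table from simulation runs
#'
#' One "cell" per run x sampled step, genes as columns -- the shape embedding
#' tools (UMAP and friends) expect.
#'
#' @param traces list of `sim_trace` objects.
#' @param subsample_every sampling stride (default 50).
#' @return data.frame with columns `run_id`, `step`, then one column per gene.
#' @export
synthetic_cells <- function(traces, subsample_every = 50) {
  rows <- lapply(traces, function(tr) {
    n_steps <- ncol(tr$values) - 1L
    steps <- seq(0L, n_steps, by = as.integer(subsample_every))
    v <- t(tr$values[, steps + 1L, drop = FALSE])
    data.frame(run_id = tr$run_id, step = steps, v, check.names = FALSE)
  })
  do.call(rbind, rows)
}
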