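test_that("expression CSV + metadata round-trips through the readers", {
  dir <- withr::local_tempdir()
  m <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  ds <- expression_dataset(m, c("A", "A", "B", "B"), c(0, 0.1, 0.5, 0.6))
  paths <- write_expression(ds, file.path(dir, "m.csv"), file.path(dir, "meta.csv"))
  ds2 <- read_expression(paths[1], paths[2])
  expect_equal(length(ds2$gene_ids), 3)
  expect_equal(length(ds2$cell_ids), 4)
  expect_equal(ds2$matrix, ds$matrix)
  expect_equal(ds2$cluster_of, ds$cluster_of)
  expect_equal(ds2$clusters, c("A", "B"))
})

test_that("reader errors name the offending cell / refuse bad values", {
  dir <- withr::local_tempdir()
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  write.csv(data.frame(gene_id = rownames(m), m), file.path(dir, "m.csv"),
            row.names = FALSE)
  meta <- data.frame(cell_id = c("c1", "c2"), cluster = "A", pseudotime = c(0, 1))
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  expect_error(read_expression(file.path(dir, "m.csv"), file.path(dir, "meta.csv")),
               "c3")

  meta3 <- data.frame(cell_id = paste0("c", 1:3), cluster = "A",
                      pseudotime = c(0, -1, 2))
  write.csv(meta3, file.path(dir, "meta3.csv"), row.names = FALSE)
  expect_error(read_expression(file.path(dir, "m.csv"), file.path(dir, "meta3.csv")),
               "non-negative")

  expect_error(expression_dataset(matrix(c(1, NaN), 1, 2,
                                         dimnames = list("g", c("c1", "c2"))),
                                  c("A", "A"), c(0, 1)),
               "NA/NaN")
})

test_that("MTX input with sidecar name files loads a 2000-cell dataset", {
  dir <- withr::local_tempdir()
  set.seed(1)
  n_cells <- 2000
  m <- Matrix::rsparsematrix(7, n_cells, density = 0.2,
                             rand.x = function(n) round(abs(rnorm(n)), 2))
  Matrix::writeMM(m, file.path(dir, "x.mtx"))
  writeLines(paste0("g", 1:7), file.path(dir, "x_genes.txt"))
  writeLines(paste0("c", seq_len(n_cells)), file.path(dir, "x_cells.txt"))
  meta <- data.frame(cell_id = paste0("c", seq_len(n_cells)),
                     cluster = rep(c("A", "B"), length.out = n_cells),
                     pseudotime = seq(0, 1, length.out = n_cells))
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  ds <- read_expression(file.path(dir, "x.mtx"), file.path(dir, "meta.csv"))
  expect_equal(length(ds$cell_ids), 2000)
  expect_equal(length(ds$gene_ids), 7)
})

test_that("GRN edge lists round-trip and reject bad sign tokens", {
  net <- random_network(12, 0.15, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grn(net, path)
  net2 <- read_grn(path)
  expect_equal(net2$edges, net$edges)

  expect_error(grn(data.frame(regulator = c("A", "A"), target = c("B", "B"),
                              sign = c(1, -1))),
               "conflicting")

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(regulator = "A", target = "B", sign = "activator"),
            bad, row.names = FALSE)
  expect_error(read_grn(bad), "activation, repression")
})

test_that("trace subsampling writes floor(steps/k)+1 columns plus metadata", {
  g <- grn(data.frame(regulator = "A", target = "A", sign = 1))
  tr <- simulate_grn(g, c(A = 1),
                     sim_params(n_steps = 1800, n_runs = 1, seed = 1))[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path, subsample_every = 50)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(ncol(df), 1 + floor(1800 / 50) + 1)  # gene col + steps 0,50,...,1800
  expect_equal(colnames(df)[2], "0")
  expect_equal(colnames(df)[ncol(df)], "1800")
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  expect_equal(meta$dt, tr$dt)
  expect_equal(meta$run_id, 1)

  write_trace(tr, path, subsample_every = 1)
  expect_equal(ncol(read.csv(path, check.names = FALSE)), 1 + 1801)
})

test_that("multi-run writer emits one file per run plus a combined long table", {
  g <- toggle_grn()
  traces <- simulate_grn(g, c(A = 1, B = 1),
                         sim_params(n_steps = 100, n_runs = 5, seed = 2))
  dir <- withr::local_tempdir()
  long_path <- write_traces(traces, dir, subsample_every = 10)
  expect_length(list.files(dir, pattern = "^trace_run[0-9]+\\.csv$"), 5)
  long <- read.csv(long_path)
  expect_setequal(unique(long$run_id), 1:5)
  expect_equal(nrow(long), 5 * 2 * (floor(100 / 10) + 1))
})
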