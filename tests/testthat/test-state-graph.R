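make_cluster_ds <- function(profiles, pt_centers, n_per = 20, noise = 0.2,
                            seed = 1) {
  set.seed(seed)
  k <- ncol(profiles)
  n <- k * n_per
  cl <- rep(colnames(profiles), each = n_per)
  pt <- rep(pt_centers, each = n_per) + runif(n, 0, 0.05)
  m <- matrix(0, nrow(profiles), n,
              dimnames = list(rownames(profiles), sprintf("cell%03d", 1:n)))
  for (i in seq_len(n)) {
    m[, i] <- pmax(0, profiles[, cl[i]] + rnorm(nrow(profiles), 0, noise))
  }
  expression_dataset(m, cl, pt)
}

test_that("single-cluster dataset yields a trivial one-node graph", {
  m <- matrix(runif(20), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  ds <- expression_dataset(m, rep("only", 5), runif(5))
  sg <- build_transition_graph(ds)
  expect_equal(sg$nodes, "only")
  expect_equal(nrow(sg$edges), 0)
  expect_equal(sg$root, "only")
  expect_equal(enumerate_trajectories(sg), list("only"))
})

test_that("auto-built graph matches the exhaustive parent-search oracle", {
  # oracle: for each non-root cluster, best Pearson correlation among all
  # clusters with strictly smaller mean pseudotime
  for (seed in 1:5) {
    set.seed(seed * 100)
    k <- 5
    profiles <- matrix(runif(6 * k, 0, 5), 6, k,
                       dimnames = list(paste0("g", 1:6), paste0("cl", 1:k)))
    ds <- make_cluster_ds(profiles, pt_centers = seq(0.1, 0.9, length.out = k),
                          seed = seed)
    sg <- build_transition_graph(ds)
    mean_pt <- sapply(ds$clusters, function(c) mean(ds$pseudotime_of[ds$cluster_of == c]))
    mean_ex <- sapply(ds$clusters, function(c) rowMeans(ds$matrix[, ds$cluster_of == c]))
    root <- names(which.min(mean_pt))
    expect_equal(sg$root, root)
    for (c in setdiff(ds$clusters, root)) {
      cand <- ds$clusters[mean_pt < mean_pt[c]]
      sims <- sapply(cand, function(p) cor(mean_ex[, c], mean_ex[, p]))
      expect_equal(sg$edges$parent[sg$edges$child == c],
                   cand[which.max(sims)],
                   info = sprintf("seed %d cluster %s", seed, c))
    }
    # spanning tree rooted at the minimal-pseudotime cluster
    expect_equal(nrow(sg$edges), k - 1)
    expect_true(all(setdiff(sg$nodes, sg$root) %in% sg$edges$child))
  }
})

test_that("chain A->B->C is recovered when profiles drift along pseudotime", {
  profiles <- cbind(A = c(5, 0, 0), B = c(3, 3, 0), C = c(0, 3, 3))
  rownames(profiles) <- paste0("g", 1:3)
  ds <- make_cluster_ds(profiles, pt_centers = c(0.1, 0.5, 0.9), seed = 3)
  sg <- build_transition_graph(ds)
  expect_equal(sg$edges[order(sg$edges$child), ],
               data.frame(parent = c("A", "B"), child = c("B", "C")),
               ignore_attr = TRUE)
  expect_equal(sg$terminals, "C")
  expect_equal(enumerate_trajectories(sg), list(c("A", "B", "C")))
})

test_that("user graphs: cycles rejected, DAGs flagged, terminals validated", {
  expect_error(validate_user_graph(data.frame(parent = c("A", "B"),
                                              child = c("B", "A"))),
               "cycle")

  expect_message(
    sg <- validate_user_graph(data.frame(parent = c("R", "R", "X", "Y"),
                                         child = c("X", "Y", "Z", "Z")),
                              root = "R"),
    "multiple parents")
  expect_equal(sg$terminals, "Z")

  expect_error(validate_user_graph(data.frame(parent = "A", child = "B"),
                                   root = "A", terminals = "A"),
               "not leaves")
})

test_that("myeloid-shaped 7-node tree yields one trajectory per terminal", {
  edges <- data.frame(
    parent = c("CMP", "CMP", "CMP", "MEP", "GMP", "GMP"),
    child = c("MK", "MEP", "GMP", "erythrocytes", "monocytes", "granulocytes"))
  sg <- validate_user_graph(edges, root = "CMP")
  expect_equal(length(sg$nodes), 7)
  expect_setequal(sg$terminals, c("MK", "erythrocytes", "monocytes", "granulocytes"))
  trajs <- enumerate_trajectories(sg)
  expect_length(trajs, 4)
  expect_true(all(sg$nodes %in% unlist(trajs)))
  expect_true(all(vapply(trajs, function(p) p[1] == "CMP", TRUE)))
})

test_that("pseudotime-backward edges warn and pinned non-minimal roots warn", {
  profiles <- cbind(A = c(5, 0), B = c(0, 5))
  rownames(profiles) <- c("g1", "g2")
  ds <- make_cluster_ds(profiles, pt_centers = c(0.1, 0.9), seed = 4)
  expect_warning(validate_user_graph(data.frame(parent = "B", child = "A"),
                                     root = "B", ds = ds),
                 "later to earlier")
  expect_warning(build_transition_graph(ds, root = "B"), "minimal mean pseudotime")
})
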