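test_that("soft heaviside has the right midpoint, tails and monotonicity", {
  expect_equal(soft_heaviside(1, 10, 1), 0.5)
  expect_equal(soft_heaviside(0, 10, 1), 1 / (1 + exp(10)))
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(soft_heaviside(x, 10, 1)) > 0))
})

test_that("fuzzy production reduces to the Boolean rule at saturation", {
  sp <- sim_params()
  sat <- c(0, sp$m / sp$gamma)
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    regs <- paste0("R", 1:k)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    edges <- data.frame(regulator = regs, target = "T", sign = signs)
    edges <- rbind(edges, data.frame(regulator = regs, target = regs, sign = 1))
    g <- grn(edges)
    states <- expand.grid(rep(list(0:1), k))
    for (i in seq_len(nrow(states))) {
      s <- unlist(states[i, ])
      x <- stats::setNames(c(sat[s + 1], 0), c(regs, "T"))
      got <- round(production_activity(g, "T", x, sp))
      names(s) <- regs
      expect_equal(got, naive_rule(regs[signs > 0], regs[signs < 0], s),
                   info = sprintf("rep %d state %s", rep, paste(s, collapse = ",")))
    }
  }
})

test_that("a noise-free self-activator settles at m/gamma within 1%", {
  g <- grn(data.frame(regulator = "A", target = "A", sign = 1))
  sp <- sim_params(sigma = 0, n_steps = 500, n_runs = 1, seed = 1)
  tr <- simulate_grn(g, c(A = 1), sp)[[1]]
  # t = 5/gamma corresponds to step 500 at dt = 0.01
  expect_lt(abs(tr$values["A", "500"] - sp$m / sp$gamma) / (sp$m / sp$gamma), 0.01)
  # from OFF with no noise it stays near zero (production ~ H(0))
  tr0 <- simulate_grn(g, c(A = 0), sp)[[1]]
  expect_lt(max(tr0$values), 0.01)
})

test_that("the toggle switch resolves (1,1) into both exclusive fates", {
  g <- toggle_grn()
  sp <- sim_params(n_steps = 600, n_runs = 200, seed = 5)
  traces <- simulate_grn(g, c(A = 1, B = 1), sp)
  finals <- vapply(traces, function(tr) {
    paste((tr$values[, ncol(tr$values)] >= sp$theta) + 0L, collapse = "")
  }, "")
  expect_setequal(unique(finals), c("10", "01"))
  expect_gt(min(table(finals)), 20)   # both fates well represented
})

test_that("expression stays non-negative under heavy noise", {
  net <- random_network(6, 0.4, seed = 9)
  sp <- sim_params(sigma = 1.5, n_steps = 300, n_runs = 10, seed = 2)
  traces <- simulate_grn(net, stats::setNames(rep(1, 6), net$genes), sp)
  expect_true(all(vapply(traces, function(tr) all(tr$values >= 0), TRUE)))
})

test_that("knockout clamps are bit-exact and windowed; OE forces production", {
  g <- toggle_grn()
  sp <- sim_params(n_steps = 300, n_runs = 3, seed = 7)
  ko <- perturbation("A", "knockout")
  traces <- simulate_grn(g, c(A = 1, B = 1), sp, list(ko))
  for (tr in traces) expect_true(all(tr$values["A", ] == 0))

  # windowed knockout: free before the window, exactly 0 inside it
  kow <- perturbation("A", "knockout", start_step = 100, end_step = 300)
  tr <- simulate_grn(g, c(A = 1, B = 0), sp, list(kow))[[1]]
  expect_gt(max(tr$values["A", 1:100]), 0.5)
  expect_true(all(tr$values["A", 102:301] == 0))

  # overexpression keeps production maximal: B rises to m/gamma even though
  # its repressor A starts ON
  oe <- perturbation("B", "overexpression")
  spq <- sim_params(sigma = 0, n_steps = 600, n_runs = 1, seed = 1)
  tro <- simulate_grn(g, c(A = 1, B = 0), spq, list(oe))[[1]]
  expect_gt(tro$values["B", "600"], 0.98 * spq$m / spq$gamma)
})

test_that("identical seeds give identical traces; different seeds differ", {
  g <- toggle_grn()
  sp <- sim_params(n_steps = 200, n_runs = 4, seed = 11)
  t1 <- simulate_grn(g, c(A = 1, B = 1), sp)
  t2 <- simulate_grn(g, c(A = 1, B = 1), sp)
  expect_identical(lapply(t1, `[[`, "values"), lapply(t2, `[[`, "values"))
  sp2 <- sim_params(n_steps = 200, n_runs = 4, seed = 12)
  t3 <- simulate_grn(g, c(A = 1, B = 1), sp2)
  expect_false(identical(t1[[1]]$values, t3[[1]]$values))
})

test_that("state classification labels steps and terminal states correctly", {
  profiles <- cbind(S1 = c(1, 1), S2 = c(1, 0), S3 = c(0, 1))
  rownames(profiles) <- c("A", "B")
  g <- toggle_grn()
  sp <- sim_params(n_steps = 400, n_runs = 30, seed = 13)
  traces <- simulate_grn(g, c(A = 1, B = 1), sp)
  labs <- vapply(traces, function(tr) {
    classify_states(tr, profiles, terminals = c("S2", "S3"), sp)$terminal
  }, "")
  expect_true(all(labs %in% c("S2", "S3")))
  expect_length(unique(labs), 2)

  cl <- classify_states(traces[[1]], profiles, terminals = c("S2", "S3"), sp,
                        subsample_every = 50)
  expect_equal(cl$steps, seq(0, 400, by = 50))
  expect_equal(cl$labels[1], "S1")   # starts at the (1,1) profile

  # a run that matches no terminal profile exactly is "other"
  p2 <- cbind(S1 = c(1, 1), T1 = c(0, 0))
  rownames(p2) <- c("A", "B")
  labs2 <- classify_states(traces[[1]], p2, terminals = "T1", sp)$terminal
  expect_equal(labs2, "other")

  # equidistant tie goes to the earliest profile column
  ptie <- cbind(X = c(1, 0), Y = c(0, 1))
  rownames(ptie) <- c("A", "B")
  g1 <- grn(data.frame(regulator = c("A", "B"), target = c("A", "B"), sign = 1))
  spq <- sim_params(sigma = 0, n_steps = 10, n_runs = 1, seed = 1)
  tr11 <- simulate_grn(g1, c(A = 1, B = 1), spq)[[1]]
  expect_equal(classify_states(tr11, ptie, terminals = "X", spq)$labels[1], "X")
})
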