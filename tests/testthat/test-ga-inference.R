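test_that("rule evaluation matches the naive oracle and rejects empty rules", {
  regs <- c("A", "B", "C")
  signs <- expand.grid(rep(list(c(-1, 0, 1)), 3))
  states <- expand.grid(rep(list(0:1), 3))
  for (i in seq_len(nrow(signs))) {
    a <- unlist(signs[i, ])
    names(a) <- regs
    if (all(a == 0)) {
      expect_error(boolean_rule_eval(a, c(A = 1, B = 1, C = 1)), "regulator")
      next
    }
    for (j in seq_len(nrow(states))) {
      s <- unlist(states[j, ])
      names(s) <- regs
      expect_equal(boolean_rule_eval(a, s),
                   naive_rule(regs[a > 0], regs[a < 0], s),
                   info = sprintf("signs %s state %s",
                                  paste(a, collapse = ","),
                                  paste(s, collapse = ",")))
    }
  }
})

test_that("evaluation set = one pair per edge plus one self-pair per terminal", {
  profiles <- chain_profiles()
  sg <- chain_state_graph()
  es <- build_evaluation_set(profiles, sg, "B")
  expect_equal(ncol(es$states), 3)   # 2 edges + 1 terminal
  expect_equal(es$required, c(1, 1, 1))
  expect_equal(colnames(es$states), c("cA->cB", "cB->cC", "cC->cC"))

  sg2 <- validate_user_graph(data.frame(parent = c("R", "R"), child = c("X", "Y")),
                             root = "R")
  p2 <- rbind(R = c(1, 0, 0), X = c(0, 1, 0), Y = c(0, 0, 1))
  colnames(p2) <- c("R", "X", "Y")
  es2 <- build_evaluation_set(p2, sg2, "X")
  expect_equal(ncol(es2$states), 4)  # 2 edge pairs + 2 terminal self-pairs

  my <- validate_user_graph(data.frame(
    parent = c("CMP", "CMP", "CMP", "MEP", "GMP", "GMP"),
    child = c("MK", "MEP", "GMP", "ery", "mono", "gran")), root = "CMP")
  pm <- matrix(0, 1, 7, dimnames = list("g", my$nodes))
  expect_equal(ncol(build_evaluation_set(pm, my, "g")$states), 6 + 4)
})

test_that("the 3-gene worked example reproduces hand-computed fitness", {
  profiles <- chain_profiles()
  sg <- chain_state_graph()
  es <- build_evaluation_set(profiles, sg, "B")
  p <- ga_params()

  single <- subnetwork_fitness(c(A = 1, B = 0, C = 0), es, p)
  expect_equal(single$agreement, 2 / 3)
  expect_equal(single$fitness, 2 / 3)   # nnz 1 == round(0.4 * 3): no penalty

  pair <- subnetwork_fitness(c(A = 1, B = 1, C = 0), es, p)
  expect_equal(pair$agreement, 1)
  expect_equal(pair$fitness, 1 - p$edge_penalty_weight)

  # brute force over all 3^3 - 1 configs: optima are exactly {A+,B+}, {A+,C+}
  bf <- exhaustive_subnetwork_search("B", c("A", "B", "C"), profiles, sg, p)
  opt <- apply(bf$optima, 1, function(r) paste(names(r)[r != 0], r[r != 0], collapse = " "))
  expect_setequal(opt, c("A 1 B 1", "A 1 C 1"))

  cfg <- infer_subnetwork("B", c("A", "B", "C"), profiles, sg,
                          ga_params(seed = 7, generations = 60))
  expect_equal(cfg$agreement, 1)
  expect_equal(cfg$fitness, bf$fitness)
})

test_that("GA is deterministic and solves degenerate self-regulation", {
  profiles <- chain_profiles()
  sg <- chain_state_graph()
  a <- infer_subnetwork("B", c("A", "B", "C"), profiles, sg, ga_params(seed = 3))
  b <- infer_subnetwork("B", c("A", "B", "C"), profiles, sg, ga_params(seed = 3))
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$history, b$history)

  always_on <- matrix(1L, 1, 3, dimnames = list("X", colnames(profiles)))
  cfg <- infer_subnetwork("X", "X", always_on, sg, ga_params(seed = 1, generations = 20))
  expect_equal(cfg$assignment, c(X = 1))
  expect_equal(cfg$agreement, 1)
})

test_that("GA matches brute force on random small instances", {
  set.seed(31)
  hits <- 0
  n_cases <- 12
  for (i in seq_len(n_cases)) {
    k <- sample(4:6, 1)
    n_cl <- sample(3:5, 1)
    profiles <- matrix(sample(0:1, k * n_cl, replace = TRUE), k, n_cl,
                       dimnames = list(paste0("g", 1:k), paste0("s", 1:n_cl)))
    sg <- validate_user_graph(
      data.frame(parent = paste0("s", 1:(n_cl - 1)), child = paste0("s", 2:n_cl)),
      root = "s1")
    target <- paste0("g", sample(k, 1))
    p <- ga_params(seed = 100 + i, generations = 150)
    cfg <- infer_subnetwork(target, rownames(profiles), profiles, sg, p)
    bf <- exhaustive_subnetwork_search(target, rownames(profiles), profiles, sg, p)
    if (cfg$fitness >= bf$fitness - 1e-9) hits <- hits + 1
  }
  expect_gte(hits, n_cases - 1)
})

test_that("compilation unions edges and repairs regulator-free genes", {
  mk_cfg <- function(target, assignment) {
    structure(list(target = target, assignment = assignment,
                   fitness = 1, agreement = 1, history = 1),
              class = "subnetwork_config")
  }
  g <- suppressMessages(compile_grn(list(
    mk_cfg("T1", c(A = 1, B = -1)),
    mk_cfg("T2", c(C = 1, D = 1)),
    mk_cfg("X", numeric(0)))))
  expect_equal(nrow(g$edges), 5)
  expect_true(any(g$edges$regulator == "X" & g$edges$target == "X" & g$edges$sign == 1))
  # simulation invariant: every target regulated
  expect_true(all(c("T1", "T2", "X") %in% g$edges$target))

  expect_error(compile_grn(list(mk_cfg("T1", c(A = 1)), mk_cfg("T1", c(B = 1)))),
               "duplicate")
})

test_that("fitness never exceeds 1 and agreement is bounded by construction", {
  profiles <- chain_profiles()
  sg <- chain_state_graph()
  es <- build_evaluation_set(profiles, sg, "A")
  set.seed(41)
  for (i in 1:25) {
    a <- sample(c(-1, 0, 1), 3, replace = TRUE)
    names(a) <- c("A", "B", "C")
    if (all(a == 0)) a["A"] <- 1
    f <- subnetwork_fitness(a, es)
    expect_lte(f$agreement, 1)
    expect_lte(f$fitness, 1)
  }
})
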