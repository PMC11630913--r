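# Independent oracles and tiny fixture builders, deliberately written as
# plain loops so they share no code with the implementation they check.

# repressor-dominant rule, naive form: activators `act`, repressors `rep`
# (character vectors), state a named 0/1 vector
naive_rule <- function(act, rep, state) {
  a <- length(act) == 0
  for (r in act) if (state[[r]] == 1) a <- TRUE
  for (r in rep) if (state[[r]] == 1) return(0L)
  if (a) 1L else 0L
}

# all fixed points of an edge list, by looping over every state
naive_fixed_points <- function(edges, genes) {
  n <- length(genes)
  fps <- list()
  for (i in 0:(2^n - 1)) {
    s <- as.integer(intToBits(i)[1:n])
    names(s) <- genes
    ok <- TRUE
    for (g in genes) {
      act <- edges$regulator[edges$target == g & edges$sign == 1]
      rep <- edges$regulator[edges$target == g & edges$sign == -1]
      if (naive_rule(act, rep, s) != s[[g]]) { ok <- FALSE; break }
    }
    if (ok) fps[[length(fps) + 1]] <- s
  }
  if (!length(fps)) return(matrix(integer(0), 0, n, dimnames = list(NULL, genes)))
  do.call(rbind, fps)
}

toggle_grn <- function() {
  grn(data.frame(regulator = c("A", "B"), target = c("B", "A"),
                 sign = c(-1, -1)))
}

# the 3-gene worked chain: clusters A -> B -> C with profiles
# A = (1,1,0), B = (0,1,1), C = (0,0,1) across the three clusters
chain_profiles <- function() {
  p <- rbind(A = c(1, 1, 0), B = c(0, 1, 1), C = c(0, 0, 1))
  colnames(p) <- c("cA", "cB", "cC")
  p
}

chain_state_graph <- function() {
  validate_user_graph(data.frame(parent = c("cA", "cB"), child = c("cB", "cC")),
                      root = "cA")
}

# small clustered dataset with deterministic structure for selection tests:
# 3 clusters x `n_per` cells; `late` gene ON only in the last cluster,
# `flat` gene constant, `noise` gene pure noise
selection_dataset <- function(n_per = 60, seed = 42) {
  set.seed(seed)
  k <- 3
  n <- k * n_per
  cl <- rep(c("c1", "c2", "c3"), each = n_per)
  pt <- rep(0:2, each = n_per) + runif(n)
  late <- ifelse(cl == "c3", 5, 0) + abs(rnorm(n, 0, 0.3))
  flat <- rep(1, n)
  noise <- abs(rnorm(n))
  m <- rbind(late = late, flat = flat, noise = noise)
  colnames(m) <- sprintf("cell%03d", seq_len(n))
  expression_dataset(m, cl, pt)
}
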