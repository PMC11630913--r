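# statecircuit

Executable Boolean gene regulatory networks from single-cell trajectories.

## The problem

Given clustered, pseudotime-annotated scRNA-seq data, most network-inference
tools output a (weighted) edge list and are judged by edge recovery. But an
edge list is not a model of differentiation: simulated as a dynamical system,
inferred networks routinely fail to reach the steady states corresponding to
the terminal cell types in the very data they were trained on. `statecircuit`
is for researchers in developmental biology and cell-fate engineering who
want the network itself to *run*: it infers a signed Boolean GRN whose
dynamics progress through the observed cell states and stabilize at the
observed terminal states, then simulates it — including in-silico knockouts
and overexpression — to predict shifts in fate proportions.

## The method

1. **State graph.** Clusters become a rooted tree: root = minimal mean
   pseudotime (or user-pinned), each cluster attached to the
   earlier-pseudotime cluster with the most similar mean expression profile
   (Pearson). Curated DAGs are accepted as input.
2. **Dynamic TFs.** A gene is kept if a GAM smooth `expr ~ s(pseudotime)` is
   significant (BH-adjusted p < 0.05) on some trajectory, it is expressed in
   ≥ 10% of cells of some cluster, and log2 max/min cluster means ≥ 2.
3. **Boolean profiles.** Cluster means, binarized per gene by exact 1-D
   two-means.
4. **GA inference.** Per target gene *g*, a genetic algorithm searches signed
   regulator assignments `a ∈ {-1, 0, +1}^n` maximizing

   `fitness(a) = agreement(a) − w·|nnz(a) − round(d·n)|`

   where agreement is the fraction of state-graph transitions `(u → v)` (plus
   terminal fixed-point requirements) on which the Boolean rule

   `g = (no activators ∨ ∃ activator ON) ∧ (∀ repressors OFF)`

   reproduces g's observed status. Subnetworks are compiled into one GRN.
5. **Simulation.** Euler–Maruyama integration of
   `dx_g = (m·B_g(x) − γ·x_g)dt + σ dW`, where `B_g` evaluates the Boolean
   rule with fuzzy operators over soft-heaviside activities
   `H(x) = 1/(1+e^{−k(x−θ)})` (OR = max, AND = min, NOT = 1−x). Knockouts
   clamp production and state to 0; overexpression clamps production to max.
6. **Attractors & evaluation.** Asynchronous Boolean simulation (compiled
   kernel) counts reachable fixed points; brute-force enumeration serves as
   the exact oracle; edge metrics, F1-maximizing threshold sweeps,
   steady-state similarity and trace cross-correlation quantify agreement
   with references.

See `vignettes/executable-grn-inference.Rmd` for assumptions, defaults, and
numerical conventions.

## Worked example

A mutual-repression toggle between two fate-determining factors, started
from the double-positive progenitor state:

```r
library(statecircuit)

tg <- grn(data.frame(regulator = c("Gata1", "Cebpa"),
                     target    = c("Cebpa", "Gata1"),
                     sign      = c(-1, -1)))

ss <- find_steady_states(tg, c(Gata1 = 1, Cebpa = 1), n_runs = 10000, seed = 1)
ss$fixed_points
#>    Gata1 Cebpa
#> 01     0     1
#> 10     1     0
ss$reach_count
#>   01   10
#> 4996 5004
```

Two fixed points, reached in near-equal proportion — the unstable
double-positive state resolves stochastically. The continuous simulator
shows the same fate split, and a knockout redirects it completely:

```r
sp <- sim_params(n_steps = 600, n_runs = 200, seed = 1)
profiles <- cbind(progenitor = c(1, 1), erythroid = c(1, 0), myeloid = c(0, 1))
rownames(profiles) <- c("Gata1", "Cebpa")

traces <- simulate_grn(tg, c(Gata1 = 1, Cebpa = 1), sp)
table(vapply(traces, function(tr)
  classify_states(tr, profiles, c("erythroid", "myeloid"), sp)$terminal, "")) / 200
#> erythroid   myeloid
#>     0.515     0.485

ko <- simulate_grn(tg, c(Gata1 = 1, Cebpa = 1), sp,
                   list(perturbation("Gata1", "knockout")))
table(vapply(ko, function(tr)
  classify_states(tr, profiles, c("erythroid", "myeloid"), sp)$terminal, "")) / 200
#> myeloid
#>       1
```

With `Gata1` knocked out, every run commits to the myeloid profile — the
qualitative signature of a lineage-determining repressor pair.

The full pipeline (expression + metadata in, GRN + simulations out) is
exposed as `run_fixtures()`, `run_infer()`, `run_simulate()`,
`run_evaluate()` driven by a YAML config, and as a thin CLI at
`inst/cli/statecircuit.R` with subcommands `fixtures`, `infer`, `simulate`,
`perturb`, `attractors`, `evaluate`.

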