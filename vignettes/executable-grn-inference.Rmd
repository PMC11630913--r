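---
title: "Executable Boolean GRNs from single-cell trajectories: models and methods"
author: "statecircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Executable Boolean GRNs from single-cell trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statecircuit)
```

## The problem

Most regulatory-network inference methods are scored on edge recovery, yet
the networks they output often cannot *run*: simulated as dynamical systems,
they fail to reproduce the steady states that correspond to the terminal cell
types in the data they were trained on. `statecircuit` takes the opposite
starting point: it infers a signed Boolean gene regulatory network (GRN)
whose dynamics are required to progress through the observed sequence of cell
states and to stabilize at the observed terminal states, and it ships the
stochastic simulator that executes the result, including in-silico knockouts
and overexpression.

The inputs are the three artifacts a standard single-cell trajectory analysis
already produces: a normalized expression matrix (genes x cells), per-cell
cluster labels, and per-cell pseudotime. Normalization is the user's
responsibility: the package assumes the matrix is already on the scale the
user wants means and fold changes computed on (the synthetic fixtures use
linear-scale values with ON means around 5, mimicking log1p-normalized
counts).

## The inference model, step by step

### Cell-state transition graph

Clusters are organized into a rooted tree. The root is the cluster with
minimal mean pseudotime unless the user pins it (developmental knowledge
routinely overrides pseudotime, so a non-minimal pinned root is a warning,
not an error). Processing clusters in ascending mean pseudotime, each one is
attached to the already-placed cluster whose mean expression profile
correlates with it most strongly (Pearson, over all genes; ties broken by
smaller pseudotime gap, then label; zero-variance profiles fall back to
Euclidean distance). The published method states only that it uses
"pseudotemporal ordering and expression profile similarity"; Pearson
correlation on cluster means is this package's concrete choice, and
auto-built graphs are restricted to trees — the simplest structure consistent
with the biology the method targets. User-supplied graphs may be DAGs (a
state reachable from two progenitors), but must be acyclic and rooted;
cyclic differentiation processes should be cut into linear segments before
use.

### Dynamically expressed TFs

A gene enters the network when (1) a generalized additive model
`expression ~ s(pseudotime)` (fitted with `mgcv`, basis dimension 5 by
default) has a Benjamini–Hochberg-adjusted smooth-term p-value below 0.05 in
at least one root-to-terminal trajectory, fitted on that trajectory's cells
only; (2) at least one cluster expresses it in at least 10% of cells; and
(3) the log2 ratio between the highest and lowest cluster mean (pseudocount
0.01) is at least 2. The adjustment procedure (BH) and the logarithm base
(2) are package choices — the source method says only "adjusted P-value" and
"log-fold change"; with natural logarithms the default of 2 would be a
considerably stricter filter. Constant genes are assigned p = 1 rather than
failing, so degenerate fits never abort a run. These filters only remove
genes: under a pure-noise null the expected selected fraction is bounded by
the adjusted-p threshold.

### Boolean activity profiles

Selected genes are averaged per cluster and binarized gene-by-gene with an
exact 1-D two-means split of the cluster means (exhaustive over the sorted
split points, so deterministic; ties prefer the larger low group). Two-means
was chosen because it is scale-free and parameter-free: it is invariant to
positive affine rescaling of a gene's means, so it behaves identically on
log- or linear-scale input. Genes whose cluster means span less than 1e-6
binarize to all-zero — a constant gene must not become a phantom always-on
regulator. Clusters with identical Boolean profiles trigger a warning:
indistinct clusters give the optimizer contradictory transition evidence.

### Boolean rule semantics

Every gene's rule has the same repressor-dominant AND-of-OR form: the target
is ON iff (it has no activators OR at least one activator is ON) AND every
repressor is OFF. This form evaluates in time linear in the number of
regulators — the property that makes the simulator scale to dense networks —
and it is the only rule family the genetic algorithm searches over, so the
attractor analysis interprets inferred networks under exactly the logic they
were inferred with.

### Evaluation pairs and the GA

For each target gene, the state graph is compiled into evaluation pairs: one
per edge `(u, v)` — the parent cluster's full Boolean profile must drive the
target to its status in the child — plus one self-pair per terminal cluster,
which forces terminal profiles to be fixed points of the eventual network.
The root receives no self-pair: an initial state is allowed (indeed
expected) to be unstable. In branching graphs sibling edges can impose
contradictory requirements on one parent profile; agreement below 1 is then
expected and correct — the stochastic simulator is what resolves fate
choice.

The genetic algorithm searches chromosomes in `{-1, 0, +1}^n` (one locus per
candidate regulator). Fitness is

```
agreement - w * | nnz - round(ideal_density * n) |
```

with `agreement` the fraction of evaluation pairs reproduced, `w = 0.01` and
`ideal_density = 0.4` by default. Operators are conventional and fully
configurable: tournament selection (size 3), uniform crossover (applied to
half the offspring), per-locus mutation at rate `1/n` resampling uniformly
among the other two values, elitism of 1, population 200, 300 generations,
all under a caller-supplied seed. Chromosomes that lose their last regulator
are repaired by activating one random locus, because every gene in a
simulable network needs at least one regulator. Ties among equal-fitness
chromosomes resolve deterministically: fewer edges first, then a fixed
lexicographic order over loci (none < activation < repression in candidate
order) — so identical seeds and inputs give byte-identical networks. On
candidate sets small enough to enumerate (`exhaustive_subnetwork_search`,
up to 10 candidates), the GA's best fitness can be checked against the true
optimum; the packaged benchmark does this for every target it infers.

Per-target subnetworks are unioned into one GRN; any gene left without a
regulator receives a self-activation edge, reported via a message.

## The simulator

Expression follows an Euler–Maruyama discretization of

```
dx_g = (m * B_g(x) - gamma * x_g) dt + sigma dW,    x_g >= 0
```

where `B_g` evaluates the gene's Boolean rule with fuzzy operators: each
regulator's activity is the soft heaviside `H(x) = 1/(1 + exp(-k (x -
theta)))`, OR is max, AND is min, NOT is `1 - x` (Goedel semantics — linear
cost, and exactly the Boolean rule at saturated inputs). Defaults: `m = 2`,
`gamma = 1`, `k = 10`, `theta = m/(2 gamma) = 1`, `sigma = 0.3`, `dt = 0.01`,
1800 steps, 200 runs. The ON initial level is the saturated value
`m/gamma`; `theta` sits halfway between OFF and ON. Noise is additive
Gaussian with reflection at zero; each run draws from its own stream seeded
`seed + run_id - 1`, so runs are reproducible individually and independent
of execution order. A knockout clamps both the production term and the
state to zero inside its window (applied after the update, hence bit-exact
zero, and downstream rules see the gene as OFF); an overexpression clamps
the production term to its maximum but lets decay dynamics act, so the
trace relaxes to `m/gamma`.

Two numerical consequences are worth knowing. First, with `sigma = 0` the
continuous system's stable equilibria binarize (at threshold `theta`) to
exactly the Boolean network's fixed points on the fixture families shipped
with the package; the correspondence test excludes equilibria with any
coordinate within 0.05 of `theta`, because perfectly symmetric initial
states (the toggle switch started at ON/ON) converge to a saddle at
`(theta, theta)` whose binarization is a coin flip in principle. Second,
`dt * gamma < 1` is enforced as a stability bound.

Simulated states are labelled against cluster profiles by binarizing at
`theta` and taking the minimum-Hamming-distance cluster (ties to the
earliest cluster in state-graph order, deterministically); a run's *final*
state must match a terminal profile exactly to receive its label, otherwise
it is `"other"`.

## Attractor analysis

Steady states are found by asynchronous Boolean simulation: repeatedly pick
one gene uniformly at random and apply its rule, stopping at a state fixed
under all rules (checked each step) or after 1000 single-gene updates —
runs trapped in cyclic attractors report as non-converged, and "steady
state" in this package always means fixed point. The inner loop is compiled
(Rcpp) with one `std::mt19937` stream per run, and every fixed point
reported by the stochastic search is re-verified in R against all rules;
`enumerate_fixed_points` provides the exact brute-force oracle up to 20
genes. Steady-state similarity between two networks averages, over the
reference's fixed points, the best per-gene agreement with any inferred
fixed point; a reference with *no* steady state scores 1 only when the
inferred set is also empty.

## The synthetic fixture generator, and what it does not emulate

`random_network` samples `round(density * n^2)` directed signed edges
(self-edges allowed, density defined over ordered pairs *including*
self-edges) and repairs regulator-free nodes with a self-activation.
`expression_from_profiles` turns a Boolean state sequence into cells:
`cells_per_cluster = 100` cells per state, ON level 5, Gaussian noise SD
0.5 truncated at zero, optional dropout, pseudotime = state index plus
uniform jitter. These defaults mimic the statistical structure the inference
consumes — cluster-separable profiles ordered in pseudotime — and nothing
else: no transcriptional bursting, no mean–variance relation, no doublets,
no batch effects. Passing tests on these fixtures demonstrates correctness
of the machinery, not robustness to the full noise anatomy of real
single-cell data.

The planted-recovery benchmark (`planted_recovery`) makes three design
commitments, each because the alternative makes the planted problem
ill-posed rather than hard:

* **Synchronous trajectories.** The profile sequence is generated by
  synchronous updates (`synchronous_trajectory`), so each state's profile
  determines every gene's status in the next state — the transition property
  the evaluation pairs assert. An asynchronous walk changes one gene per
  step, so consecutive "cluster profiles" systematically violate that
  property and even the true network scores poorly against them. The
  asynchronous walk (`boolean_trajectory`) remains available and is what the
  attractor analysis uses.
* **Known chain graph.** The generated trajectory is linear, and the
  benchmark passes that chain to the inference explicitly (the same
  user-graph route a curated real-data analysis uses). Reconstructing the
  chain from profile correlations is a different, harder problem whose
  failures would be misattributed to the GA.
* **Instances with a terminal state.** Networks with no reachable fixed
  point (e.g. pure oscillators) fall outside the model class — the method
  requires at least one terminal steady state — so the generator resamples
  until the trajectory converges, and the chosen initial state is the one
  (over all `2^n` for n <= 6) giving the longest converging trajectory,
  since short trajectories leave most edges unidentifiable in principle.

Recovery is scored on what the data can identify: edges whose deletion
changes their target's rule output on at least one visited state, restricted
to genes that vary along the trajectory; targets with no identifiable true
edge are excluded from both sides (the method must emit a rule for every
gene, so edges there are forced); and regulators with identical status
sequences across the visited states are treated as interchangeable. The GA's
`ideal_density` is set to the generator's density in this benchmark, because
the expected in-degree of a planted instance is known; the package-wide
default stays at 0.4.

## Parameters that matter

| parameter | default | unit / range | why |
|---|---|---|---|
| `adj_p_threshold` | 0.05 | probability | BH-adjusted GAM smooth significance |
| `min_pct_expressed` | 0.1 | fraction of cells | drops never-expressed genes |
| `min_logfc` | 2 | log2 units | requires real between-cluster contrast |
| `ideal_density` | 0.4 | fraction of candidates | soft prior on regulators per gene |
| `edge_penalty_weight` | 0.01 | fitness units | keeps the penalty below one evaluation pair |
| `population_size` / `generations` | 200 / 300 | — | conventional GA budget; fitness histories are logged for convergence checks |
| `m`, `gamma` | 2, 1 | expression/time, 1/time | set the ON level `m/gamma = 2` |
| `k` | 10 | 1/expression | steep enough to recover Boolean logic at saturation |
| `theta` | `m/(2 gamma)` | expression | ON/OFF midpoint |
| `sigma` | 0.3 | expression/sqrt(time) | enough noise to resolve fate choices |
| `dt`, `n_steps` | 0.01, 1800 | time | 18 decay time-constants per run |
| `n_runs` | 200 | — | stochastic fate proportions |
| attractor `n_runs` | 10000 | — | steady-state census |

`edge_penalty_weight = 0.01` is deliberately an order of magnitude below the
value of a single evaluation pair (at least `1/|pairs|`), so edge parsimony
only ever arbitrates between equal-agreement configurations.

## Degenerate inputs and tie-breaking, collected

* Constant gene in the GAM: p = 1 (not an error). Basis dimension shrinks
  automatically when pseudotime has few distinct values.
* Zero-variance cluster profile in graph building: Euclidean fallback.
* Effectively constant gene in binarization (< 1e-6 span): all-zero.
* Binarization split ties: larger low group.
* GA fitness ties: fewer edges, then fixed locus order.
* Hamming-label ties in classification: earliest state-graph cluster.
* Empty chromosome after mutation: one random locus activated.
* Gene without regulators after compilation: self-activation added, logged.
* Threshold-degenerate equilibria (any coordinate within 0.05 of `theta`)
  are excluded from the continuous-vs-Boolean correspondence check.

## Problem sizes used by the packaged checks

The shipped tests and the acceptance script run entirely on generated data
at desk scale, sizes chosen so the full battery completes in a few minutes:
truth tables to 4 regulators (1280 cases), 50 random networks of 3–8 genes
with 10000-run attractor searches, 30 planted 5-gene replicates at density
0.2 (100 cells per state, noise SD 0.5), 8 networks of 2–6 genes for the
continuous/Boolean correspondence, and 200-run toggle simulations. The
published application scale (12 TFs, 7 clusters, 200 runs of 1800 steps)
simulates in under two seconds here, so the binding cost is the GA search,
which is linear in generations and targets.

## Known limitations

* Inference quality is only as good as the clustering: clusters without
  distinct Boolean profiles give the GA contradictory evidence (the package
  warns but proceeds).
* Inferred interactions are functional, not necessarily direct physical
  binding.
* Only fixed-point attractors are modelled; limit cycles are reported as
  non-convergence, never as states.
* The transition-graph auto-builder is a heuristic; for systems with
  convergent or cyclic differentiation it should be replaced by a curated
  graph.
* Perturbation predictions inherit the Boolean abstraction: dosage effects
  below the ON/OFF contrast are invisible.
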