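---
title: "Ergodic-Set sensitivity of threshold Boolean networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ergodic-Set sensitivity of threshold Boolean networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbnsens)
```

This vignette documents the model implemented by `tbnsens`, the choices
made where the framework leaves the design open, and what the package's
synthetic experiments do and do not establish about real regulatory
networks.

## The model and its assumptions

A threshold Boolean network over `n` genes is a ternary matrix
`A[i, j] ∈ {-1, 0, +1}` (effect of gene `j` on gene `i`; diagonal
self-interactions are legitimate entries). States are binary vectors
updated synchronously: gene `i` computes its field
`h_i = Σ_j A[i, j] x_j` and switches on when `h_i > 0`, off when
`h_i < 0`, and keeps its state on a tie — a consensus rule that leaves
unregulated genes frozen. The dynamics are deterministic on a finite
state space, so every trajectory reaches a fixed point or limit cycle.

The long-term description rests on a separation of timescales: the
deterministic dynamics relax to an attractor much faster than expression
noise flips single genes. Under that assumption only transitions *between
attractors* matter. From each state of each attractor every one of the
`n` single-gene flips is followed back to an attractor; the Ergodic Sets
(ESs) are the terminal strongly connected components of the resulting
digraph. At least one ES always exists; more than one is rare (the test
suite's scan over seeded random 8-gene networks at density 0.5 bounds
the multi-ES fraction well below 10%), and the sensitivity score is left
undefined in that case rather than averaged over ESs.

On an ES the flip process is a Markov chain over attractors. Transition
probabilities normalize flip counts per originating attractor by all
`L × n` flips, which encodes a uniform distribution of time over the `L`
states of a cycle. The chain is irreducible by construction; it may be
periodic, so the stationary vector is obtained by a direct linear solve
of `πP = π, Σπ = 1` rather than by power iteration.

## The penalty factor

Flipping a gene on while other genes actively repress it (`h_i < 0` at
the pre-flip state), or off while it is actively sustained (`h_i > 0`),
is biologically less likely than a flip along a neutral field. Such
flips are down-weighted by `λ ∈ (0, 1]` before normalization, giving the
penalized stationary distribution `π̃`; `λ = 1` recovers `π` exactly, and
`π̃ → π` continuously as `λ → 1`.

Three choices here were genuinely open and are fixed as follows:

* **Field evaluated pre-flip.** "Actively repressed" describes the state
  the gene is in at the moment it flips, so the penalty tests `h_i` at
  the source state, not after the flip.
* **Topology is penalty-free.** The penalty reweights probabilities; it
  never removes a transition. A reading in which penalized flips are
  deleted (`λ = 0`) could disconnect the flip graph and change the ES
  structure itself, which is why `λ = 0` is excluded from the domain.
* **Per-attractor normalization.** All `L × n` flips of an attractor
  share one normalizer. A per-state variant coincides with it for fixed
  points and differs negligibly for the short cycles that dominate
  evolved ensembles.

The magnitude of `λ` is a modelling degree of freedom with no canonical
value; the package default is `λ = 0.5`, every experiment logs the value
used, and sensitivity analyses can be re-run at `λ = 1` (plain `π`) to
bound the `λ`-dependence of any conclusion. For the toggle-switch
example the wild-type occupancy is `λ`-independent, but its mutants are
not: `S = 1/4` at `λ = 1` versus `S = 5/28` at `λ = 0.5`, a useful
reminder that reported sensitivities are `(λ)`-qualified.

## The sensitivity score and its decomposition

The distance between two ESs is the total variation between their
stationary occupancies over the union of attractors, with attractors
matched by their exact canonical state sequence (cycles sharing some but
not all states are different attractors). Total variation makes the
score interpretable: `d ∈ [0, 1]`, `1` means disjoint attractor support,
and a fixed-point attractor that survives in at most half of all
deletion mutants can contribute at most about `0.5` through attractor
loss alone — matching the observed ceiling for networks whose ESs hold
only fixed points.

`S(A)` is the unweighted mean of `d` over all single-edge deletion
mutants. Mutants with multiple ESs are skipped and logged by default
(`multi_es_policy = "skip_mutant"`): they are rare, their distance is
undefined, and erroring out would abort long evolutionary runs.

Each mutant's displaced mass is decomposed into the four mechanisms
(destabilized, new-in-ES, demoted-from-ES, redistributed); the four sum
to `2d` because moved mass is counted where it left and where it landed.
When aggregating over an ensemble the package reports mean *absolute
contributions* to `S` (each network's four contributions sum to its `S`,
so the ensemble means sum to the subset's mean sensitivity). This is the
form in which displaced-mass breakdowns of evolved ensembles are quoted;
reporting shares of `S` instead would make the three groups sum to 1
identically and carry strictly less information. The subset threshold
for these summaries defaults to `min_S = 0.5`, motivated by evolved
discounted ensembles typically exceeding that sensitivity; it is a
configurable reporting choice, not part of the score.

## Evolution

`adaptive_walk()` is a strict hill climb: a uniformly chosen entry is
reassigned to one of the two other ternary values with equal
probability, and the proposal is kept only if its fitness is strictly
better. Strict improvement (no neutral drift) reflects the observation
that walks reach a local peak quickly; a run budget of 1000 moves is the
default. Proposals with multiple ESs are rejected but still consume
budget, keeping run lengths comparable across conditions. Only the
current network is required to have a single ES; its deletion mutants
are handled by the skip policy. Optimum detection compares fitness to
the exact bounds 0 and 1 within `1e-12`; distances of structurally
identical ESs are computed from identical linear systems and are exactly
zero in floating point, so the `S = 0` count is not tolerance-sensitive.

The discounted objective `S × D`, with `D` the inverse mean attractor
length of the wild-type ES, suppresses the dominant sensitivity strategy
of building one long fragile limit cycle and forces mass displacement
through the other mechanisms.

## The synthetic generator and what the tests show

All experiments run on synthetic networks: each entry is independently
nonzero with probability `density` (default 0.5) and then `±1` with
equal probability, self-interactions included. The default density keeps
initial networks unsaturated, which matters because robustness
evolutions tend to add edges. These are the study conditions of every
ensemble statistic the package reports; they emulate dense random
regulatory wiring, not the degree distributions, sparsity or modularity
of curated biological networks. Passing ensemble tests therefore
establish properties of the method under these conditions — directional
claims (balance increases with evolved sensitivity, discounting
suppresses long cycles) should transfer, but absolute rates (e.g. the
fraction of robustness evolutions reaching `S = 0` exactly, or the ES
size profile of the optima, both of which are sensitive to the initial
edge density) should not be read as universal constants. One concrete
observation from the test suite: at density 0.5 many optimally robust
networks evolve "free" genes with no inputs, which double the ES per
free gene; denser starts make such optima rarer and push the optimally
robust class towards single-attractor ESs.

## Numerical and reproducibility choices

* Gene 1 occupies the least significant bit of the integer state code;
  attractors are rotated to start at their smallest state code and
  ordered by it, making every tie-break deterministic and letting
  attractors of different networks be matched by value.
* Exhaustive enumeration is guarded at `n ≤ 24` genes, and chain
  construction at 4096 attractors, to bound memory; the analyses in the
  tests use `n ∈ {4, 5, 6, 8}`.
* Stationary solves use dense LU on systems no larger than the attractor
  count; residuals `‖πP − π‖∞` are checked below `1e-9` in the suite.
* All randomness flows through R's RNG. `random_tbn()`,
  `adaptive_walk()` and `run_ensemble()` accept seeds and restore the
  global RNG state; ensembles derive per-run seeds from the master seed
  up front and record them, so any run can be reproduced in isolation.
* The test suite's problem sizes — 200-network oracle comparisons
  against an independent brute-force implementation, ensembles of
  100–200 walks, Monte-Carlo occupancy checks with batch-mean standard
  errors — were chosen to give stable statistics at desk scale; the
  shipped acceptance script runs the robustness experiment at its full
  1000-run scale.

## Known limitations

* Synchronous updates only; asynchronous schedules can change both the
  attractor set and the flip graph.
* Single-flip noise and single-edge-deletion mutations; multi-flip
  perturbations and gain-of-interaction mutations are out of scope.
* Sensitivity is undefined for multi-ES networks rather than
  generalized; the ES-count switch scan (`es_switch_scan()`) locates the
  single-edge boundary between the regimes but the score itself does not
  cross it.
* The penalty magnitude `λ` is not identifiable from the model; every
  quantitative result should cite the `λ` it was computed under.
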