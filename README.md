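# tbnsens

Mutational sensitivity of threshold Boolean networks via Ergodic Sets.

`tbnsens` is for systems biologists and network theorists who model gene
regulatory circuits as threshold Boolean networks (TBNs) and want to ask:
*how much does the long-term behaviour of a circuit change when it loses a
single regulatory interaction?* Robust circuits shrug off such mutations;
sensitive ones — a dynamical signature that has been proposed for
pluripotent stem cells — can differentiate into qualitatively different
behaviours through single edge changes. The package measures that
sensitivity, decomposes how the change happens, and evolves networks
in-silico towards either extreme.

## The model

A network of `n` genes is a ternary interaction matrix `A` with
`A[i, j] ∈ {-1, 0, +1}`, the effect of gene `j` on gene `i`. Gene states
are binary and update synchronously by consensus of their inputs:

    h_i(x) = Σ_j A[i, j] x_j
    x_i' = 1 if h_i > 0,  0 if h_i < 0,  x_i if h_i = 0

The deterministic dynamics settle onto attractors (fixed points or limit
cycles). Under weak expression noise — rare single-gene flips from an
attractor state — the system hops between attractors; an **Ergodic Set
(ES)** is a strongly connected set of attractors with no outgoing flip
transitions, and captures the network's entire long-term behaviour. On an
ES the flip process is a finite Markov chain: flip counts between
attractors are normalized per originating attractor by the `L × n`
possible flips (time is spent uniformly over a cycle's `L` states), and
flips that oppose active regulation (turning a gene on against a negative
field, or off against a positive one) can be down-weighted by a penalty
`λ ∈ (0, 1]`. Its stationary vector `π` (penalized: `π̃`) gives the
long-run occupancy of each attractor.

The **sensitivity** of a single-ES network is

    S(A) = mean over deletion mutants A' of  d(E_A, E_A')
    d = ½ Σ_c |π_A(c) − π_A'(c)|     (total variation, attractors matched
                                      by their exact state sequence)

`S = 0` is maximal robustness, `S = 1` maximal sensitivity. Each mutant's
displaced mass is decomposed four ways: (1) wild-type ES attractors
destabilized entirely, (2) mass on new attractors in the mutant ES,
(3) wild-type ES attractors retained by the mutant but excluded from its
ES, (4) redistribution over shared attractors. An optional discount
`D = 1 / (mean ES attractor length)` penalizes sensitivity achieved purely
through fragile long limit cycles. `adaptive_walk()` hill-climbs `S` (or
`S × D`) over single-edge changes, accepting only strict improvements.

## Worked example: the toggle switch

The mutual-repression toggle `A = [[0, -1], [-1, 0]]` (shipped as
`inst/extdata/toggle.tsv`):

```r
library(tbnsens)
A <- read_tbn(system.file("extdata", "toggle.tsv", package = "tbnsens"))
enumerate_attractors(A)
#> <fixed point, length 1>: 00
#> <fixed point, length 1>: 10
#> <fixed point, length 1>: 01
ergodic_sets(A, lambda = 1)[[1]]
#> <Ergodic Set: 3 attractor(s), mean length 1>
#>   pi = 0.5000   0
#>   pi = 0.2500   1
#>   pi = 0.2500   2
deletion_sensitivity(A, lambda = 1)
#> <deletion sensitivity: S = 0.2500 over 2/2 mutants (lambda = 1, penalized)>
#>   wild-type ES: 3 attractor(s), mean length 1; S x D = 0.2500
```

All three states with one or zero genes on are fixed points; their flip
graph is strongly connected, so they form one ES. The off-off state
receives every return flip, hence `π = (1/2, 1/4, 1/4)`. Deleting either
repressive edge keeps all three attractors but shifts the occupancy, and
the total-variation distance is exactly `1/4` for both mutants — all of it
through redistribution (method 4) — so `S = 0.25`.

Evolving a random 5-gene network for sensitivity while discounting long
limit cycles:

```r
w <- adaptive_walk(random_tbn(5, density = 0.5, seed = 11), "maximize",
                   use_discount = TRUE, seed = 11)
w
#> <adaptive walk (maximize, discounted): fitness 0.2732 -> 0.7935 in
#>  10 accepted / 1000 proposed moves>
```

Ten accepted single-edge changes almost triple the discounted sensitivity;
`run_ensemble()` batches such walks with reproducible per-run seeds and
`decomposition_summary()` aggregates the displacement breakdown of the
evolved networks.

A thin command-line wrapper over these functions is installed at
`system.file("cli", "tbn.R", package = "tbnsens")` with subcommands
`generate`, `analyze`, `sensitivity`, `evolve`, `ensemble` and
`scan-switches`.

## Scope

Synchronous ternary-threshold dynamics only: no asynchronous or
probabilistic update schemes, no weighted real-valued interactions, and no
θ-thresholded (TES) variant of the Ergodic Set.
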