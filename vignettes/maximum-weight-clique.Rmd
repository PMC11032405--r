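---
title: "Exact maximum weight clique search: model, bounds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact maximum weight clique search: model, bounds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwclique)
```

## The problem

Given an undirected graph on vertices `1..n` with positive integer vertex
weights `W`, the maximum weight clique problem (MWCP) asks for a pairwise
adjacent vertex subset maximizing the sum of its weights. It generalizes
maximum clique (all weights 1) and is NP-hard, but exact solutions on graphs
of practical size are routinely possible with branch-and-bound if the upper
bound used for pruning is tight. The motivating application is molecular:
in a correspondence (modular product) graph of two molecules, vertices are
compatible atom pairs and heavy cliques are large common substructures, so
an exact weighted-clique solver is a core primitive for structure comparison
in drug discovery.

`mwclique` implements the search twice, deliberately:

* the **branch-and-bound solver** (`solve_mwc()`, `max_clique_weight()`,
  `max_clique_dyn_weight()`), C++ under an R surface, which is the tool; and
* a **naive brute-force reference** (`brute_force_mwc()`), pure R, no
  pruning beyond adjacency, which exists so that the tool can be proven
  right on every instance small enough to enumerate. The two share no code.

## The bounding procedure

At every search node the candidate set `R` (vertices that extend the current
clique `Q`) is processed by `color_sort_weight()`:

1. **Greedy coloring.** Scanning `R` in its incoming order, each vertex
   joins the lowest-indexed color class containing none of its neighbors,
   opening a new class when needed. Classes are independent sets, so any
   clique inside `R` uses at most one vertex per class.
2. **Class weights and cumulative bounds.** Class `k` records
   `weight(C[k]) = max{W[v] : v ∈ C[k]}`. A clique whose highest class
   index is `k` therefore weighs at most `ub_k = Σ_{j≤k} weight(C[j])`, and
   every vertex of class `k` is assigned this `wcolor = ub_k` as its bound.
   The sum runs over class *indices* `1..k`, not over the `k` lightest
   classes: only the prefix reading gives a valid bound, because a clique
   through a class-`k` vertex can pick one vertex from each lower-indexed
   class at most.
3. **Prune threshold.** `min_k_w` is the smallest `k` with
   `ub_k > weight(Qmax) − weight(Q)`; if none exists the whole set is
   pruned (`min_k_w = maxno + 1`). Vertices in classes below `min_k_w`
   cannot produce an improving clique *among themselves*: any clique lying
   entirely in classes `1..min_k_w−1` weighs at most `ub_{min_k_w−1}`,
   which by minimality does not exceed the incumbent gap. (A clique mixing
   pruned and unpruned vertices can of course beat the gap — it is found
   when the search branches on its unpruned members, which carry nonzero
   bounds.)
4. **Reordering.** The pruned vertices move to the front of `R`, keeping
   their incoming relative order, with `wcolor = 0`; the remaining classes
   follow in class order, vertices in within-class insertion order. The
   output `wcolor` sequence is therefore nondecreasing.

The expansion loop (`Expand`) pops the *last* candidate `p` — the one with
the highest bound — and descends only while
`weight(Q) + wcolor(p) > weight(Qmax)`. Because bounds are nondecreasing
along the candidate order, the first failing test closes the entire level,
not just one branch. When the candidate set of a branch is empty and
`weight(Q)` beats the incumbent, `Qmax` is replaced and the new weight is
appended to the incumbent history (a strictly increasing sequence ending at
the optimum — the anytime profile that `autoplot()` draws).

With all weights 1, `ub_k = k` and the machinery reduces exactly to the
classical greedy-coloring bound for unweighted maximum clique; the test
suite asserts this reduction.

## The dynamic variant

The static variant computes degrees and the vertex order once, at the root.
The dynamic variant re-tightens the bound where it pays: before coloring a
nonempty candidate set `Rp`, it computes `T[level]` — the fraction of all
expansion steps so far that were taken at depths `1..level` — and, while
`T[level] < tlimit`, recomputes each candidate's degree *within the induced
subgraph* `G(Rp)` (an `O(|Rp|²)` pass) and stably re-sorts `Rp` by
decreasing induced degree before coloring. Large candidate sets occur at
low depths, where `T[level]` is small, so the default `tlimit = 0.025`
confines the extra work to the part of the tree where tighter bounds
prevent the most misdirected descent.

Two details pin the bookkeeping down. A *step* is one iteration of the
expansion loop (one vertex selection), counted at the level where the
selection occurs, including the iteration whose bound test fails; and
`T` is evaluated just before the coloring call, treating an empty step
count as 0. These choices affect only where the gate fires — never the
result: `tlimit = 0` disables the gate entirely and is verified to be
step-for-step identical to the static variant, and both variants are
verified to return the brute-force optimum across the random suite.

## Vertex ordering, tie-breaks and determinism

The root order is vertices sorted by decreasing degree, with ties broken
*stably* by the incoming order (for the root, ascending vertex id). Every
subsequent candidate set inherits the relative order of its parent, which
the coloring consumes as-is — bound tightness depends on this inherited
order. All tie-breaks in the package are stable and there is no randomness
anywhere in the solver, so a run is fully determined by the input and its
vertex numbering. Vertex numbering does affect running time, which is why
benchmarking is defined over random relabelings (below).

Internally vertices are `1..n` throughout the R layer — R's native indexing,
and also the DIMACS convention, so ids in files, results and printed cliques
all agree; the translation to 0-based indices happens only at the C++
boundary. Recursion depth equals the clique number plus one at most; the
C++ stack handles the graph sizes this package targets (thousands of
vertices) comfortably.

## Weights and arithmetic

Weights are positive integers stored as doubles. Every quantity the
algorithm compares is a sum of at most `n` weights, exact in double
arithmetic up to 2^53 — far beyond the `n × 2×10⁶` scale the default
weight model can produce — so no integer overflow consideration arises.

## What the generator emulates

`random_weighted_graph(n, p, mu, sigma)` draws each of the `choose(n, 2)`
unordered pairs independently (in fixed lexicographic order, so a seed
fully determines the graph): an edge appears when a fresh uniform draw on
`[0, 1)` falls below `p`. Weights are normal draws with mean
`mu = 1,000,000` and standard deviation `sigma = 200,000`, rounded
half-away-from-zero to integers; a draw that would round below 1 is
rejected and redrawn. Rejection (rather than clamping) preserves the
distribution's shape, and at the default scale it essentially never
triggers (a nonpositive draw is a 5-sigma event); the positivity guarantee
matters only for deliberately extreme settings such as `mu = 5, sigma = 10`,
which the tests exercise. `set_random_weights()` applies the same weight
model to an existing structure — the standard way of turning unweighted
benchmark instances (e.g. DIMACS collections) into weighted ones.

What the generator does *not* emulate: G(n, p) edges are independent,
while real correspondence graphs and curated benchmark families have
structured edge sets (communities, near-cliques planted by construction),
and real application weights are not i.i.d. normal. Passing the random
suite therefore demonstrates exactness and order-invariance of the solver,
not performance claims on structured instances.

## The worked seven-vertex instance

`example_graph()` is a small instance whose complete search trace is
documented: root coloring classes {4,2}, {1,5}, {3,6}, {7} with class
weights 7, 8, 5, 1; root bounds 21 and 20 for vertices 7 and 6; a first
incumbent {4,5,6,7} of weight 18; pruned-to-zero bounds that terminate two
levels; and the optimum {3,4,5} of weight 20 reached with partial-clique
weights 7 and 13 along the winning branch. The weight of vertex 2 is not
identifiable from that trace — vertex 2 shares its class with the heavier
vertex 4 and is always pruned — so it is exposed as a parameter (`w2`,
default 3); every traced quantity is invariant for `w2` in 1..7, which the
tests check by brute force.

## File format

`read_dimacs()`/`write_dimacs()` speak the ASCII DIMACS clique format
(`c` comments, `p edge n m`, `e i j` with 1-based ids; `p col` accepted as
a synonym, duplicate edge lines merged). Vertex weights use `v i w` lines
in the same file — a convention used by weighted-clique benchmark
distributions; unweighted files are valid and default every weight to 1.
The binary `.b` DIMACS format is out of scope.

## Benchmarking protocol

`run_benchmark()` implements shuffle-and-repeat measurement: each solver
runs `repeats` times per instance (default 100), each repeat on a freshly
relabeled copy — structure preserved, vertex numbers permuted — and the
report is mean ± sample SD of wall time plus the optimum and an
all-runs-agree flag (which must be true for exact solvers, and is asserted
in tests; times themselves are hardware-dependent and never asserted).
All solvers see the same shuffled instances. Speedup of algorithm A against
reference B is `mean time(B) / mean time(A)`. A user-supplied solver
function can be benchmarked alongside the built-in variants, which is the
intended hook for comparing an external reference solver; optional
floor/cap arguments reproduce the cosmetic time-capping convention of
published tables and default to off.

## Problem sizes used by the test suite

The suite proves exactness by oracle equivalence on 200 random graphs with
`n` in 10..25 and densities {0.2, 0.5, 0.8, 0.9} under the full-scale
weight model, checks order-invariance with 100 random relabelings of an
`n = 60`, `p = 0.7` instance, verifies the unweighted reduction on graphs
up to `n = 20`, and validates the coloring bound and prune threshold by
exhaustive clique enumeration on graphs up to `n = 15`. These sizes keep
exhaustive verification exact while exercising every code path; the solver
itself handles far larger instances (a dense `n = 100` graph solves in
well under a second).

## Known limitations

* Exactness is the contract; there is no anytime/heuristic mode for graphs
  too large to solve exactly.
* No recoloring or class-renumbering refinements beyond the greedy pass;
  the bound is the plain prefix-sum coloring bound.
* Edge-weighted or real-weighted problems are out of scope; weights are
  positive integers on vertices.
* The dense adjacency matrix used by the C++ core favors the dense
  benchmark regime; memory grows as `n²`, which is the practical size
  limit (tens of thousands of vertices).
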