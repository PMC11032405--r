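# mwclique

Exact maximum weight clique search in vertex-weighted undirected graphs.

In a vertex-weighted graph each vertex `v` carries a positive integer weight
`W[v]`; a *maximum weight clique* is a pairwise-adjacent vertex subset `Q`
maximizing `weight(Q) = Σ_{v∈Q} W[v]`. The problem is NP-hard and shows up
across bioinformatics and cheminformatics: in a correspondence (product)
graph built from two molecules, heavy cliques encode maximum common
substructures, and in protein interaction networks weighted cliques pick out
cohesive functional modules. `mwclique` provides an exact branch-and-bound
solver for this problem, together with the plumbing a practitioner needs
around it: DIMACS file I/O, a random weighted-graph generator, a brute-force
reference solver, and a shuffle-and-repeat benchmarking harness with a
command-line interface.

## The algorithm

The solver is a depth-first branch-and-bound over the clique lattice with a
weighted greedy-coloring upper bound:

- **Coloring bound.** At every search node the candidate set `R` is greedily
  partitioned into color classes `C[1..maxno]` (each an independent set, so
  any clique takes at most one vertex per class). Class `k` records the
  maximum weight of its vertices, and every vertex of class `k` is assigned
  the cumulative bound `wcolor = ub_k = Σ_{j≤k} weight(C[j])` — an upper
  bound on the weight of any clique within `R` whose highest class is `k`.
- **Pruning.** With a growing clique `Q` and incumbent `Qmax`, classes whose
  prefix bound cannot close the gap `weight(Qmax) − weight(Q)` are pruned:
  their vertices move to the front of `R` in their incoming order with
  `wcolor = 0`. The expansion loop always takes the *last* vertex `p` of the
  reordered `R` and descends only while
  `weight(Q) + wcolor(p) > weight(Qmax)`; since bounds are nondecreasing
  along `R`, the first failure closes the whole level.
- **Dynamic variant.** At levels where the fraction of expansion steps spent
  at depths `1..level` is below `tlimit` (default 0.025), candidate degrees
  are recomputed inside the induced subgraph `G(Rp)` and the candidates
  re-sorted (stably) by decreasing induced degree before coloring. This
  tightens bounds where candidate sets are largest; both variants always
  return the same optimal weight.

The search is exact and deterministic; running *time* (never the result)
depends on the initial vertex order, which is why the benchmark harness
reruns every instance under random vertex shuffles.

## A worked example

The package ships a seven-vertex instance whose search trace exercises every
part of the algorithm:

```r
library(mwclique)

g <- example_graph()
g
#> <weighted_graph> 7 vertices, 14 edges, max degree 5, total weight 28

res <- max_clique_weight(g)
res
#> <clique_result> weight 20, 3 vertices (static)
#> clique: 3 4 5
#> steps: 13; incumbents: 18 20
```

The search first finds the clique {4, 5, 6, 7} of weight 18, then improves
it to the optimum {3, 4, 5} of weight 20 and proves optimality after 13
expansion steps. The coloring bounds driving this are visible directly:

```r
cs <- color_sort_weight(g)   # root call: degree-sorted vertices, empty Q/Qmax
tidy(cs)
#> # A tibble: 7 x 4
#>   position vertex color wcolor
#>      <int>  <int> <int>  <dbl>
#> 1        1      4     1      7
#> 2        2      2     1      7
#> 3        3      1     2     15
#> 4        4      5     2     15
#> 5        5      3     3     20
#> 6        6      6     3     20
#> 7        7      7     4     21
```

Vertex 7 carries the root bound 21 (= 7 + 8 + 5 + 1, the class maxima), so
no clique in the graph can weigh more than 21; the incumbent of weight 18
then prunes everything the prefix bounds cannot beat. The dynamic variant,
DIMACS round-trips and the brute-force reference give the same optimum:

```r
max_clique_dyn_weight(g)$weight      # 20
brute_force_mwc(g)$weight            # 20
solve_mwc(read_dimacs(write_dimacs(g)))$weight  # 20
```

From a shell, the same things are available as subcommands:

```sh
exec/mwclique gen --n 100 --p 0.9 --seed 7 -o dense.clq
exec/mwclique solve dense.clq --dyn
exec/mwclique oracle small.clq
exec/mwclique bench --config bench.yaml
```

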