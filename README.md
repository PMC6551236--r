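# unicent

Consensus centrality for **signed, weighted, undirected biological
networks** — microbial co-occurrence networks, gene co-expression networks,
and any other graph whose edges carry association strengths in
[−1, 1] with negative values meaning antagonism (co-exclusion).

When "importance" has no single right definition, the classic path-based
centralities disagree: betweenness finds bridges, closeness finds the
geometric middle, degree finds the densest neighbourhood, and on real
signed networks their top sets can be nearly disjoint.  `unicent`

1. extends the three indices to signed weights via **maximum
   edge-weight-product paths**: per node pair, the best positive product
   `G(i,j)` and most negative product `L(i,j)` over simple paths, found by
   a modified Dijkstra search over products;
2. de-biases each index (*backbone*) with an **iterative loop**: extract
   the most central node, remove it together with the opposite edges of its
   *stable triads* (triangles with zero or exactly two negative edges),
   recompute, until everything is unimportant; and
3. unifies the backbones' discovery traces: nodes found by all backbones
   are **universal agreements**, connected disagreement sets in which every
   backbone's pick appears exactly once become **supernodes** ("toss-ups",
   merged when they overlap), the leftovers are flagged unresolvable, and
   everything is ranked by mean discovery rank.

The backbone formulas are

    C_CLO(i) = | Σ_{j≠i} G(i,j) + L(i,j) |
    C_DEG(i) = | Σ_{j≠i} W(i,j) |
    C_BET(i) = Σ_{j,k} γ_jk(i) + λ_jk(i)

with `γ`/`λ` counting whether `i` is interior to the recorded maximum
positive/negative path of the pair `{j,k}`.  Any further centrality can be
plugged in through `register_backbone()`.

## Worked example

```r
library(unicent)

g <- generate_network(n_nodes = 30, topology = "modular", n_modules = 3,
                      seed = 42)
g
#> <signed_network: 30 nodes, 80 edges (9 negative)>

r <- matria(g)                     # iterative BET, CLO, DEG + consensus
r
#> <matria_ranking: 30 nodes -> 7 elements (6 agreed, 1 supernodes; 10 unresolvable, 11 unimportant)>

tidy(r)
#> # A tibble: 7 × 4
#>   position rank_score type      members
#>      <int>      <dbl> <chr>     <chr>
#> 1        1       1.67 node      n021
#> 2        2       5.33 node      n001
#> 3        3       6.25 supernode n010,n012|n019
#> 4        4       7    node      n017
#> 5        5       7.33 node      n003
#> 6        6       8    node      n009
#> 7        7      10    node      n004
```

Reading the output: `n021` is the consensus-most-central node (mean
discovery rank 1.67 across the three backbones).  Position 3 is a
*supernode*: the backbones split between `n019` and the pair
`{n010, n012}` — a centrality toss-up among neighbouring nodes, reported as
one ranked element with two positions rather than resolved arbitrarily.
The remaining nodes are either unresolvable disagreements or agreed
unimportant; `glance(r)` gives the full coverage accounting, and the
consensus ranking correlates positively with every backbone it unifies:

```r
v <- expanded_rank_vector(r)
sapply(r$backbones, function(bb)
  spearman(v, expanded_rank_vector(r$traces[[bb]], g)))
#>   BET   CLO   DEG
#> 0.695 0.262 0.677
```

`autoplot(r)` draws the ranked elements; `write_ranking()`,
`write_partition_json()` and `write_trace()` export everything as
TSV/JSON.  A command-line wrapper ships in `inst/cli/unicent.R`:

```sh
Rscript inst/cli/unicent.R generate --topology modular --n 126 --modules 5 --seed 7 --out net.tsv
Rscript inst/cli/unicent.R run --input net.tsv --out results
Rscript inst/cli/unicent.R correlate --inputs results.rankvec.BET.tsv,results.rankvec.MATRIA.tsv --out corr.tsv
```

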