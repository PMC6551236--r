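---
title: "Unified iterative centrality for signed weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified iterative centrality for signed weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unicent)
```

## The problem

In many biological networks -- microbial co-occurrence networks built from
thresholded correlations, gene co-expression networks -- there is no single
right definition of node "importance".  Betweenness, closeness and degree
centrality each carry a strong spatial bias (bridges, the geometric middle,
the densest component), and on real signed networks their top-ranked sets
can be nearly disjoint.  `unicent` implements a consensus procedure: each
base centrality ("backbone") is first de-biased by an iterative
extract-and-remove loop, and the backbones' discovery traces are then
reconciled into one ranked set of central nodes and *supernodes* --
explicit "toss-ups" where the algorithms disagree but the disagreement has
a structural explanation.

Throughout, a network is undirected with signed edge weights in
$[-1, 1] \setminus \{0\}$: positive weights are cooperative associations
(co-occurrence, co-expression), negative weights antagonistic ones
(co-exclusion).  Zero-weight edges are rejected at construction because a
zero weight is indistinguishable from the absence of an edge in every
formula below.

## Signed path products: gains and losses

For nodes $i, j$, let $G(i,j) \in [0,1]$ be the maximum product of edge
weights over simple paths between $i$ and $j$ whose product is positive,
and $L(i,j) \in [-1,0]$ the most negative product over simple paths whose
product is negative; both are 0 when no such path exists.  The pair
exchanges a *gain* along its best positive channel and a *loss* along its
best antagonistic channel, and both are computed independently per pair.
The three backbones are

* **closeness**: $C_{CLO}(i) = \bigl|\sum_{j \ne i} G(i,j) + L(i,j)\bigr|$,
* **degree**: $C_{DEG}(i) = \bigl|\sum_{j \ne i} W(i,j)\bigr|$ over incident
  edge weights, and
* **betweenness**: $C_{BET}(i) = \sum_{\{j,k\}} \gamma_{jk}(i) +
  \lambda_{jk}(i)$, where $\gamma_{jk}(i) = 1$ exactly when $i$ is an
  interior node of the recorded maximum positive path for the pair
  $\{j,k\}$, and $\lambda$ likewise for the negative path.

Because several maximum-product paths can tie, betweenness is made
well-defined by recording **one deterministic witness per pair and sign**:
ties (at $10^{-9}$ relative magnitude) are broken by fewer edges, then by
the lexicographically smallest node sequence; witnesses are oriented from
the lexicographically smaller endpoint.  Each pair therefore contributes 0
or 1 per sign, pairs are counted unordered (doubling them would scale every
value uniformly and cannot change a ranking), and endpoints do not count as
"interior", the standard betweenness convention.

### The bounded label search

`mod_dijkstra()` finds the labels with a best-first search over edge
products: a frontier of labels ordered by decreasing magnitude, two sign
classes per node, where extending a path multiplies its product by the edge
weight and flips the class on a negative edge.  Since $|w| \le 1$,
extension never increases magnitude, so the first label popped for a
(node, sign) slot is that slot's optimum -- the same argument that makes
Dijkstra's algorithm correct.

Two subtleties make the naive one-label-per-slot version wrong.  First,
paths must be *simple*: a walk around a negative-product cycle would
otherwise fabricate sign flips (the package tests construct a network where
a walk search would report a positive connection between a pair joined only
by negative paths).  Every label therefore carries its visited set and
never re-enters it.  Second, the optimal path to a far node may have a
*suboptimal* prefix at an intermediate node, so discarding all but the best
label per slot loses optima.  The search consequently keeps a
dominance-pruned set of labels per slot (a label is dropped only if another
has both magnitude $\ge$ and visited-set $\subseteq$), which makes it exact
-- at an exponential worst case, since maximum-product simple paths
inherit the hardness of longest-path problems.

The `width` parameter caps the surviving labels per slot and is the
tractability dial:

* `width = 0` -- unlimited, exact over simple paths; feasible for a few
  dozen nodes on sparse networks, and the right setting for verification.
* `width = 1` -- the classic single-label heuristic; demonstrably misses
  optima even on 8-node networks.
* `width = 8` -- the package default.  On the randomized verification
  ensembles in the test suite (hundreds of seeded networks up to 8 nodes,
  edge probability 0.4, mixed signs) it agrees with exhaustive path
  enumeration to $10^{-9}$ on every gain and loss, with a factor-two margin
  (width 4 already suffices there), while keeping the all-pairs
  recomputation inside the iterative loop around a hundred milliseconds at
  60 nodes and a few seconds at 126 nodes.

A bounded budget can only *lose* paths, never invent them, so bounded
labels are always lower envelopes of the exact ones in magnitude -- a
property the tests assert alongside small observed deviations on denser
24-node modular networks.  Exactness at every scale is not attainable for
this quantity; the bounded search is the method, and the exhaustive
enumerator (`brute_force_labels()`, refusing networks over 10 nodes) is its
independent referee.

## The iterative loop

`iterate()` de-biases a backbone by repetition: compute centralities,
extract the arg-max node $m$ (ties broken by lexicographically smallest
id), remove $m$, its incident edges, *and its stable-triad dependency
edges*, recompute, and stop when every remaining value is at most
`zero_tol`.  A triangle through $m$ is *stable* when it has zero or exactly
two negative edges (structural balance: two friends, or two nodes sharing
an enemy); the edge opposite $m$ in such a triangle is treated as owing its
existence to $m$ and leaves with it.  A most-central node with no stable
triads removes only itself.

Numerical choices: `zero_tol` defaults to $10^{-9}$ because closeness
values are sums of products of reals and never reach exact zero; arg-max
ties compare values exactly (the tolerance is for the stop rule, not the
comparison); stable triads are evaluated on the *current* reduced network
each iteration, and all path labels are recomputed from scratch each
iteration -- correctness over speed, which is also why the loop's cost is
the all-pairs label search times the trace length.  The loop removes one
node per iteration, so it terminates in at most $n$ iterations, and it
contains no randomness: reruns are bit-identical.

## The consensus stage

Given one discovery trace per backbone (rank = discovery order),
`matria()` classifies every node:

1. **Universal agreements** -- discovered by every backbone.
2. **Supernodes** -- over the remaining disagreement nodes, every connected
   subset (connectivity judged on the original network, since the removed
   edges already served their purpose inside the loop) whose members'
   discovering-backbone sets are pairwise disjoint and jointly cover every
   backbone exactly once.  Enumeration runs size-$k$ all-singleton subsets
   first ("triads" for $k = 3$ backbones), then smaller subsets down to
   pairs, each pass in lexicographic order.  Candidates may overlap;
   overlapping supernodes are then merged until pairwise disjoint with a
   single rule: union the position node-sets backbone-wise, then coalesce
   backbones whose node-sets coincide into one joint position.  This rule
   reproduces all published pairwise merge patterns (triad with adjacency,
   triads sharing one or two nodes, adjacencies sharing one) and their
   compositions, and extends unambiguously to any number of backbones, so
   no merge pattern needs to be rejected; a post-merge check still verifies
   that every supernode covers every backbone exactly once.  Within a
   merged supernode a node discovered by two backbones may legitimately
   occupy two positions; across supernodes, members are disjoint.
3. **Unresolvable** -- disagreement nodes absorbed by no supernode (for
   example two nodes that one backbone ranks as *both* important while two
   others split them).  These are reported but not ranked; encapsulating
   them as a further element type is deliberately not attempted.
4. **Agreed unimportant** -- nodes discovered by no backbone.

The four classes partition the node set, which the tests assert on every
generated ensemble.  Supernodes are formed after all traces complete, not
on the fly: an on-the-fly rule could pair a disagreement node with a node
that later turns out to be a universal agreement, and still could not
resolve indirect-effect disagreements.

**Ranking.**  A universal agreement scores the unweighted mean of its ranks
across all backbones.  A supernode scores the mean over its positions; a
position scores the mean, over the backbones it covers, of the rank of its
earliest-discovered member under that backbone.  Elements are sorted
ascending (lower score = more central), ties broken by lexicographically
smallest member.  Weighted averaging is left out by design.

**Rank vectors.**  For cross-method comparison, `expanded_rank_vector()`
gives every member node its element's 1-based position and every uncovered
node (unresolvable or unimportant) the tied last position (elements + 1) --
order-isomorphic to "zero centrality" for rank purposes.  `spearman()`
compares two such vectors with average-rank tie handling.

## The synthetic generators

The package ships seeded generators rather than the original biological
networks.  `generate_network(topology = "modular")` emulates a thresholded
co-occurrence network: `n_modules` planted partitions (default 5 over 126
nodes, the scale of the motivating bacterial network), one hub per module
connected positively to every module member, other intra-module pairs
present with `p_in = 0.35` and mostly positive (`neg_frac_in = 0.1`),
inter-module pairs sparse (`p_out = 0.03`) and as often antagonistic as not
(`neg_frac_out = 0.5`).  Weight magnitudes are drawn uniformly from
$[0.3, 0.95]$, the range that survives a typical correlation threshold.
`topology = "scale_free"` uses preferential attachment (2 edges per
arriving node) with the same weight sampling -- the conventional reading of
a "scale-free synthetic" test network; the original construction is not
published.  Identical arguments and seed give byte-identical networks.

What the generator does *not* emulate: correlated noise between modules,
degree-weight dependence, compositionality artefacts of relative-abundance
data, or isolated nodes (though the data model and every downstream stage
tolerate them).  Passing tests on these ensembles show the machinery is
correct and the consensus direction is right; they do not certify
biological conclusions on real data.

The fixture networks (`fixture_network()`) freeze three hand-curated cases
with annotated expected outcomes: a three-way toss-up that yields exactly
one supernode triad, a two-node toss-up that yields one adjacency
supernode, and the symbolic overlapping triad-plus-adjacencies merge chain.
The first two were selected by searching small seeded modular variants for
networks whose traces provably produce the pattern, then frozen as literal
edge lists; their annotations are verified in the tests by an independent
pure-R simulation of the whole loop (own path enumerator, own centrality
formulas, own removal loop), never by the code under test.

## Ensemble sizes used by the tests

The acceptance-style checks run at deliberate sizes: 200 seeded networks
of 4-8 nodes for oracle equivalence (brute-force enumeration is the
bottleneck), 50 networks for the backbone limit laws and the iteration
contract (10-40 nodes), 50 forty-node networks for the partition
invariants, and 20 sixty-node five-module networks for the consensus
direction check, which asks that the unified ranking correlate positively
with every backbone in at least 18 of 20 runs.  These sizes keep the whole
suite within minutes while giving each property enough replicates to fail
loudly if a rule is wrong.

## Known limitations

* Only the three path-based backbones ship; eigenvector-style signed
  centralities (PN-centrality, PageTrust) plug in through
  `register_backbone()` but are not implemented here.
* Directed networks are out of scope; so are multigraphs and edge metadata
  beyond one signed weight.
* The bounded label search is inexact in principle at large widths of
  disagreement between short and long paths; its budget is a documented,
  user-adjustable parameter rather than a hidden approximation.
* Merge semantics beyond pairwise member-sharing (exotic compositions for
  more than three backbones) follow the single generalized rule above;
  should a pathological composition ever violate the coverage invariant,
  the constructor refuses it rather than guessing.
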