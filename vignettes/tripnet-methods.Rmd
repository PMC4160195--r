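---
title: "Constructing rooted phylogenetic networks from rooted triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing rooted phylogenetic networks from rooted triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripnet)
```

## The problem

A rooted triplet `ij|k` is the smallest informative statement about rooted
evolutionary history: taxa `i` and `j` share a more recent common ancestor
with each other than either does with `k`. Triplets can be estimated from
distance matrices, sequence data, or clipped out of conflicting gene trees.
When every triplet in a set fits a single species tree, the classical
Aho/BUILD recursion reconstructs that tree in polynomial time. Real triplet
sets, however, routinely conflict — hybridization, recombination and
lateral transfer produce signals that no tree can display — and then the
natural target is a *rooted phylogenetic network*: a rooted DAG whose
indegree-2 nodes (*reticulations*) absorb the conflicting ancestry. Because
minimizing reticulations is NP-hard even for dense triplet sets, practical
methods are heuristics. The method implemented here works on *arbitrary*
triplet sets — density is never assumed — and aims for few reticulations
rather than provably fewest.

A network here obeys the usual binary degree rules: one root of indegree 0
and outdegree 2, and all other nodes with (in, out) degrees (1, 2), (2, 1)
or (1, 0), leaves distinctly labeled. The *level* of a network is the
maximum number of reticulations in any biconnected component.
`ij|k` is *displayed* by (consistent with) a network if the network
contains a subdivision of the triplet: distinct nodes `u`, `v` with four
pairwise internally node-disjoint paths `u -> i`, `u -> j`, `v -> u`,
`v -> k`.

## Height functions: the central intermediate

The algorithm funnels all triplet information through a *height function*:
a map from unordered taxon pairs to positive integers. For a tree,
`h_T(i, j) = l_T - depth(lca(i, j))` with `l_T` the longest root-to-leaf
path: cherries sit at height 1, the deepest splits at `l_T`. A triplet
`ij|k` is consistent with a tree exactly when `h(i, j) < h(i, k)` or
`h(i, j) < h(j, k)`. For a network the lowest common ancestor is not
unique; with `d(r, u)` the *longest*-path depth, the height is minimized
over all minimal common ancestors. The strict-inequality criterion then
survives only as a sufficient condition: `tripnet` ships a stored
three-leaf level-1 witness (`fix_height_counterexample()` in the test
suite; network `((k)#H1,((#H1,j),i));`) whose triplet `ij|k` is displayed
although `h(i,j) = h(i,k) = 3 > h(j,k) = 2`. The package's consistency
decision is therefore an exact subdivision search
(`triplet_consistent()`), with the height criterion used only as a fast
accept.

To obtain a height function from triplets, each `ij|k` is read as two
integer constraints `h(i,j) + 1 <= h(i,k)` and `h(i,j) + 1 <= h(j,k)`,
bounded by `1 <= h <= s`. These constraints are the arcs of a digraph
`G_tau` on taxon pairs (`build_triplet_digraph()`): the system is feasible
for some `s` iff `G_tau` is acyclic, the minimal feasible ceiling is the
longest path length plus one (`ip_min_s()`), and the layered assignment
obtained by peeling sinks (`height_from_digraph()`) dominates every
feasible solution pointwise — under a maximize-the-sum objective it is the
unique optimum (`verify_optimal_height()`). Triplet sets derived from a
distance matrix by the closest-pair rule, and triplet sets consistent with
a tree, always give acyclic digraphs. Conflicting sets may not; a
deterministic feedback-arc heuristic (`feedback_arc_removal()`) then
deletes as few arcs as it can find — shortest cycle first, removing the
lexicographically smallest arc entering a maximum-degree cycle node. An
arc into the busiest pair node encodes a constraint inflating that pair's
height, so deleting it deflates the longest paths while discarding a
single triplet's worth of information; whatever is lost is recaptured by
the final patching step.

## From heights to trees: HBUILD and binarization

`hbuild()` decides whether a tree realizes a height function: on the
complete weighted graph, remove the maximum-weight edge class; each
disconnection event becomes an internal node; a round that fails to
disconnect a multi-taxon component means no tree exists. On heights
derived from a tree-consistent triplet set this reproduces exactly the
BUILD tree — the package tests this equivalence on random trees rather
than asserting the (typographically unrecoverable) explicit bound relating
digraph and tree heights. The HBUILD tree may be multifurcating;
`binarize()` refines it deterministically (the first `k - 1` children,
ordered by smallest descendant label, move under a fresh node), which
never removes displayed triplets.

Inside the decomposition loop (below) the package uses a *relaxed* variant
of this test: weights there are inherited minima rather than fresh layered
heights, so removal rounds are allowed to continue until the component
disconnects (the same rule the decomposition itself uses), and the
resulting tree is accepted only if it displays every current triplet.
The strict one-round variant would reject instances that are plainly
tree-consistent — on the bundled 15-triplet example it would miss the
5-taxon tree that the reticulation leaf must be inserted into — while an
unchecked relaxed variant would accept trees displaying nothing; the
combination is the only reading under which the worked example proceeds
as published.

## The decomposition loop

When no tree exists the taxa are decomposed into *SN-sets*: subsets `S`
such that no triplet `ij|k` has one cherry member outside `S` while the
other cherry member and the outgroup are inside. Removing maximum-weight
edge classes of the height-weighted complete graph until components
disconnect, and recursing into non-SN components, yields a partition into
SN-sets (`sn_decompose()`). Each multi-taxon block is contracted to a
single node; triplets spanning three distinct blocks survive with block
names, and the weight between blocks is the minimum height over cross
pairs (`contract()`). A structural result guarantees the contracted
instance re-decomposes into singletons — the test suite asserts this on
every instance the pipeline produces.

If the contracted instance still admits no tree, one node must become a
*reticulation leaf*. Three criteria rank the candidates
(`select_reticulation()`):

* **I** — blocks minimizing the minimum (then the maximum) leaf-level
  height of edges leaving the block, computed on the original height
  function restricted to surviving taxa;
* **II** — among those, maximum degree in the subgraph induced by the
  globally minimum-weight contracted edges;
* **III** — among those, delete the candidate (with its triplets) and
  re-decompose: the candidates after whose removal the most multi-node
  SN-sets form win. Blocks are counted by contracted-node cardinality;
  counting original leaves instead produces ties that contradict the
  published walkthrough of the 15-triplet example.

The surviving candidate is removed and the loop repeats. When several
candidates survive all three criteria the speed mode decides: `slow`
branches on every candidate and keeps the completed run with fewest
reticulations (ties broken lexicographically), `normal` examines two
seeded-random candidates, `fast` one. `slow` is the default: desk-scale
instances are small, and the worked examples presume the best candidate is
found.

## Reassembly

Removed reticulation leaves are re-inserted in reverse order
(`insert_reticulation_leaves()`): every unordered pair of distinct edges
is tried, both edges subdivided, the two new nodes joined onto a fresh
reticulation node feeding the leaf, and the candidate displaying the most
context triplets wins (first candidate in the deterministic edge
enumeration on ties). The scoring context is the original triplet set
projected onto the current network's leaf blocks, recomputed at each
insertion — at this stage only contracted taxa exist, and the projection
form stays well defined even when contractions nest. Contracted blocks
are then expanded by running the whole algorithm on each block's
restricted triplet set and grafting the sub-network onto the block's
pendant edge (`recurse_and_expand()`); recursion depth equals the SN
nesting depth and the taxon count strictly decreases.

Finally, `patch_inconsistent()` enforces the headline guarantee. While
any input triplet is not displayed, the cherry pair carrying the most
undisplayed triplets has its pendant edges subdivided and the two new
nodes joined by an arc — tail on the lexicographically smaller leaf's
side, the reverse orientation tried if the first fails to help, and the
next-ranked pair tried if neither orientation reduces the undisplayed
set. Each accepted step adds exactly one reticulation and strictly
shrinks the undisplayed set, so termination is guaranteed; consequently
*every* output network displays 100% of its input triplets, and inputs
that fit a tree come back as a binarization of the BUILD tree with zero
reticulations. The same patching runs in the rare early exit where a
conflicting input nevertheless admits a tree for its post-feedback-arc
heights.

## Exact consistency checking

`triplet_consistent()` decides the subdivision condition exactly. In a
DAG the `v -> u` path is automatically internally disjoint from the
`u -> i` / `u -> j` paths (its interior consists of ancestors of `u`,
theirs of descendants), so the search reduces to: enumerate candidate
`v` and each `v -> k` path `P`, then ask for a `v -> u` path and two
node-disjoint `u -> {i, j}` paths avoiding `P`'s interior. The
two-disjoint-paths question is a unit-node-capacity flow solved by at
most two BFS augmentations on the split graph. The test suite proves this
decision equivalent to a brute-force enumeration of all path four-tuples
on hundreds of small random networks. Path enumeration is exponential
only in the number of reticulations a single `v -> k` pair can traverse,
which is tiny at the scales this package targets (tens of taxa).

## Synthetic data

The generators emulate the study conditions the method was designed for:

* `random_binary_tree(n, seed)` — Yule growth (uniformly chosen leaf
  splits), the standard null model for rooted tree shapes;
* `random_network(n, r, seed)` — `r` reticulations added to a Yule tree
  by subdividing two edges and joining them, rejecting cyclic placements;
* `triplets_from(source, fraction, seed)` — the displayed triplet set,
  subsampled per 3-subset to emulate sparse, non-dense input;
* `distance_matrix_from_tree(t, noise_sd, seed)` — twice the pair
  heights, an ultrametric on the tree's topology under which the
  closest-pair rule (`tcd_triplets()`) recovers exactly the tree's
  triplets; Gaussian noise (floored at `1e-6`) emulates estimation error.

What these fixtures do *not* emulate: realistic branch-length and rate
heterogeneity, sequence-level estimation error structure (noise here is
i.i.d. Gaussian on distances), or taxon sampling bias. Passing tests
therefore certify the combinatorial machinery — recovery, consistency,
determinism — not statistical performance on empirical alignments.

Problem sizes used by the test and acceptance runs — trees and networks
of 4–8 leaves, up to 3 reticulations, 100–200 replicates per property —
are the package's chosen desk scale: large enough that every code path
(branching, nested contraction, patching) is exercised, small enough that
the brute-force oracles remain exact references.

## Numerical and design choices

* Tie detection in the closest-pair triplet rule compares stored values
  exactly; no epsilon. The rule is defined on the given matrix, and
  callers holding noisy estimates can pre-round. Dense mode breaks ties
  by a seeded uniform choice among the cherries attaining the minimum.
* All randomized choices flow from a single integer seed
  (`withr::with_seed`); identical input, speed and seed give identical
  (bit-stable) serialized output.
* The serialization dialect uses `#H<k>` hybrid tags, no branch lengths,
  and children ordered by smallest descendant leaf label; parsing is
  delegated to \pkg{ape}. Serialization is deterministic for a given
  in-memory graph; across a parse/serialize round trip graphs are
  compared by leaf-colored VF2 isomorphism (`network_isomorphic()`),
  since hybrid-tag numbering is not a graph invariant.
* Degenerate inputs: taxa appearing in no triplet are carried as isolated
  digraph pair-nodes (height = ceiling) and surface as free leaves;
  one- and two-taxon recursion blocks return a leaf or cherry directly;
  an empty triplet set on `n >= 3` taxa yields a binarized star.
* The tabular surfaces (triplet sets, height tables, tidy/glance
  summaries) are tibbles, so they pipe into dplyr/ggplot2 workflows;
  trees and networks themselves are plain parent/child edge-list objects
  (`phylo_net`) — a graph, not a data frame, is the honest container for
  them.

## Limitations

* The reticulation count is heuristic: no minimality guarantee exists
  (the underlying optimization is NP-hard), and `slow` mode's branch
  scoring is itself greedy at nested branch points.
* The feedback-arc step is a heuristic for an NP-hard problem; different
  (equally defensible) cycle choices can change the height function and
  hence the output network.
* Patching can, in adversarial cases, stack several reticulations on one
  cherry pair, inflating the level beyond what a cleverer global
  construction would need.
* Scaling: the exact consistency oracle and the edge-pair insertion scan
  are quadratic-to-cubic per step in the network size; the implementation
  targets the tens-of-taxa regime, not hundreds.
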