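# tripnet

Rooted phylogenetic networks from arbitrary sets of rooted triplets.

A rooted triplet `ij|k` says that taxa `i` and `j` are more closely
related to each other than either is to `k`. When all triplets in a set
fit one species tree, the Aho/BUILD recursion finds that tree; when they
conflict — as they do under hybridization, recombination or lateral
transfer — no tree exists, and the honest summary is a **rooted
phylogenetic network** whose indegree-2 *reticulation* nodes absorb the
conflict. `tripnet` implements a nine-step heuristic that accepts an
*arbitrary* (in particular, non-dense) triplet set and returns a network
displaying **every** input triplet, using as few reticulations as it can
find. It is aimed at phylogeneticists who have triplet-level signal —
from distance matrices, gene trees, or curated datasets — and want an
explicit, checkable network rather than a forced tree.

## The method in brief

Each triplet `ij|k` imposes the height constraints
`h(i,j) + 1 <= h(i,k)` and `h(i,j) + 1 <= h(j,k)` on unordered taxon
pairs. These constraints form a digraph `G_tau` on pairs; it is acyclic
iff the system is feasible, and peeling sinks yields the layered height
function `h`, the pointwise-dominant feasible solution. The pipeline:

1. build `G_tau`, remove feedback arcs if conflicts make it cyclic, and
   compute `h`;
2. try to realize `h` as a tree (HBUILD); if that succeeds, binarize and
   stop — tree-consistent input always ends here with 0 reticulations;
3. otherwise decompose the taxa into SN-sets (subsets no triplet
   "enters" with its outgroup), contract them, and repeat;
4. when the contracted instance admits no tree, pick a *reticulation
   leaf* by three ranking criteria (pendant-edge heights, min-weight
   degree, post-deletion SN structure), remove it, and loop;
5. re-insert removed leaves as reticulations at the edge pair displaying
   the most triplets, expand contracted blocks recursively, and patch
   any still-undisplayed triplet with one extra reticulation per round
   until none remain.

Triplets can also be derived from a labeled distance matrix by the
closest-pair rule (`ij|k` iff `D_ij < min(D_ik, D_jk)`), with seeded tie
breaking to densify.

## Worked example

The package ships a 15-triplet set on taxa `i..o` that no tree can
display:

```r
library(tripnet)

path <- system.file("extdata", "example1_triplets.txt", package = "tripnet")
ts <- parse_triplets(path)
fit <- tripnet(ts, speed = "slow")
fit
#> TripNet result: 7 taxa, 1 reticulation(s), level 1
#> consistent input triplets: 15 / 15
#> ((i,(j,(k,(l)#H1))),((#H1,m),(n,o)));
```

One reticulation suffices: the network hangs leaf `l` below a
hybrid node (`#H1`) reachable both from the `(i,(j,k))` clade and from
the `(m,(n,o))` clade, which is exactly what the conflicting triplets
(`kl|j` and `kl|i` versus `lo|k` and `mn|l`) demand. The decomposition
log records the SN partition `{i}{j}{k}{l}{m}{n,o}` and the criteria
cascade `R1 = {k,l}`, `R2 = {k,l}`, `R3 = {l}` that singled out `l`.

```r
glance(fit)
#> # A tibble: 1 × 7
#>   n_taxa n_triplets n_reticulations level consistent_fraction step9_added speed
#>    <int>      <int>           <int> <int>               <dbl>       <int> <chr>
#> 1      7         15               1     1                   1           0 slow

tidy(fit)          # per-triplet consistency table
autoplot(fit)      # layered drawing, hybrid arcs dashed
```

Deriving triplets from distances instead:

```r
t <- random_binary_tree(6, seed = 1)
d <- distance_matrix_from_tree(t, noise_sd = 0)
ts <- tcd_triplets(d, dense_mode = TRUE, seed = 1)
all(tree_consistent_triplet(t, ts))
#> [1] TRUE
```

A thin command-line front end lives in `inst/exec/tripnet`
(`tripnet run --triplets FILE -o net.enwk`, plus `build`, `heights`,
`decompose`, `tcd`, `check`, `simulate`).

## Package layout

- `R/triplet-set.R`, `R/tcd.R` — triplet tibbles, file formats, the
  distance rule
- `R/triplet-digraph.R` — the pair digraph, feedback arcs, layered
  heights, the integer-program characterization
- `R/tree-builders.R` — Aho graph, BUILD, HBUILD, binarization, tree
  heights
- `R/network.R`, `R/enewick.R` — the `phylo_net` class, validation,
  level, network heights, exact triplet-consistency, eNewick I/O
- `R/sn-decomposition.R`, `R/assembly.R` — SN-sets, contraction, the
  three criteria, Steps 6-9 and the `tripnet()` driver
- `R/fixtures.R` — random trees, networks, triplet subsampling,
  ultrametric distances
- `vignettes/tripnet-methods.Rmd` — the model, the design decisions and
  their rationale, limitations
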