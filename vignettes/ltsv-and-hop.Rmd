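---
title: "Vector encodings of rooted trees and the HOP rearrangement"
author: "ltsvtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector encodings of rooted trees and the HOP rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltsvtree)
```

## The model

`ltsvtree` works with rooted phylogenetic trees in the convention that the
root is an extra node of outdegree 1; the leaves are bijectively labelled by
taxa and internal nodes have outdegree 2 (binary) or more (polytomies).
Once a *taxon order* fixes a bijection between the labels and the indices
`1..n`, every binary tree corresponds to exactly one integer vector of
length `2n` — its LTSv representation — in which each index appears twice.
The first occurrence of `i` stands for an internal node, the second for
leaf `i`; second occurrences appear in increasing order, and the first
occurrence of `i` always precedes the second occurrence of `i - 1`.

Encoding works by labelling the non-leaf nodes: the root receives `1`, and
a node whose two children have smallest descendant taxa `i > j` receives
`i`.  This labelling is always a bijection between the `n` non-leaf nodes
and the taxa, and cutting the tree at those labels decomposes it into `n`
paths, each running from the node labelled `i` down to leaf `i`.  The
vector is the concatenation of the per-path label sequences (the *lineage
taxon sequences*), separated by the second occurrences.  Decoding scans
adjacent token pairs and emits one edge per pair, so both directions run in
linear time.

```{r}
tr <- parse_newick("((1,2),(3,4));")
v <- encode_tree(tr, taxon_order(as.character(1:4)))
v
trees_equal(decode_tree(v), tr)
```

One subtlety is worth documenting: the per-path label sequence of path
`P_i` contains the labels of the nodes strictly below the path's start
node, and the first path additionally carries the root's own label `1` in
front.  Writing the start node's label on every path would duplicate
symbols and break the length-`2n` invariant; this convention reproduces
the canonical decomposition exactly (block `i` of the vector, cut just
before the second occurrence of `i`, equals the lineage taxon sequence of
taxon `i`).

## The HOP operator and its distance

A HOP move takes the first occurrence of a taxon `i >= 2` and re-inserts
it anywhere after position 1 and no later than the second occurrence of
`i - 1`.  Every such move yields a valid vector and corresponds to a
subtree prune-and-regraft on the underlying tree, so the HOP graph is a
subgraph of the SPR graph; it is connected, and neighbourhoods have
quadratic size.  We fix insertion targets in *post-removal* coordinates
(the index the token occupies in the resulting vector): counting positions
in the original vector instead would double-count
the slot that straddles the removed token; post-removal coordinates make
each (taxon, target) pair produce a distinct vector and make moves
trivially reversible.  Under this convention taxon `i` contributes
`p(i-1) - 3` moves, where `p(k)` is the position of the second occurrence
of `k`, and two moves coincide exactly when they swap two adjacent first
occurrences — which yields a closed-form neighbourhood count that
`hop_neighbourhood_size()` evaluates in linear time (it is tested against
materialized enumeration).

The HOP distance between two vectors is `n` minus the HOP similarity, the
sum of block-wise longest-common-subsequence lengths over the canonical
decompositions.  Blocks are partial permutations (no repeated symbol), so
each LCS reduces to a longest increasing subsequence computed by patience
sorting in `O(m log m)`; the whole distance costs `O(n log n)`.

```{r}
u <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
w <- ltsv(c(1, 2, 3, 1, 4, 2, 3, 4))
hop_similarity(u, w)
hop_distance(u, w)
```

When a witness subsequence is needed (for the common forest and shortest
paths), ties among equal-length LCSs are broken deterministically: the
witness occupying the earliest possible positions in the first vector is
selected via tail-LIS lengths.  For blocks `(1,3,2)` and `(1,2,3)` this
yields the witness `(1,3)`, and the interleaved LCS vector
`(1,3,1_,2_,3_,4_)` decodes — by the same path-gluing rules as tree
decoding, with unreferenced connectors kept as component roots — into the
three-component forest `(1,3)`, `(2)`, `(4)`.  Each component equals the
restriction of both input trees to the component's taxa (the restriction
sense of "common subtree"; components need not be pendant subtrees).

Shortest HOP paths are built greedily: at each step the leftmost token of
the target vector outside the current block-wise witness is moved into the
position it occupies in the target.  Each move raises the similarity by
exactly one; the suite checks path lengths against breadth-first search
over the explicit HOP graph on 4 and 5 taxa.

Degenerate input: on a single taxon only one tree exists, and the
similarity formula (which sums to block `n - 1`) would misbehave, so
`hop_distance` returns 0 directly for `n = 1`; distances otherwise range
between 0 and `n - 1`, with `n - 2` attained by the caterpillar/ladder
pair.

The HOP distance depends on the taxon order.  `mhop_heuristic()`
approximates the order-minimal distance by sampling random orders (always
including the natural sorted order); exact minimization over all `n!`
orders is conjectured intractable and only the sampling heuristic is
provided.

## Generalizations

*Annotated vectors* replace each entry by a triplet `index:name:length`
carrying the node name and the length of the entering branch, which makes
the encoding lossless for trees with metadata; the taxon order is
recoverable from the leaf triplets.  *Polytomies* are handled by labelling
a node of outdegree `k > 2` with the set of its children's minima minus
the smallest, written as a brace-group; the element count becomes
`2n + 2t` for `t` polytomy nodes and the correspondence remains
one-to-one.

*Tree-child networks* (binary, every non-leaf node has a non-reticulation
child) are encoded component-wise: removing reticulation edges leaves
`r + 1` tree components; the component roots and both parents of each
reticulation are labelled with the smallest taxon below that reticulation,
components are ordered by where their second parents sit, and the
per-component vectors are concatenated.  We keep the top component's full
vector and drop only the leading root label of reticulation-rooted
components: dropping the first element of *every* component (a literal
reading of the construction) would truncate the `r = 0` case to length
`2n - 1` and leave the smallest taxon with a single occurrence, breaking
the decoder's block-splitting.  With our convention the `r = 0` encoding
equals the plain tree encoding, a taxon occurs three times exactly when it
is the minimum of a reticulation component, and decoding (split at last
occurrences, build one path per block, glue connectors, contract
singly-referenced connectors) inverts encoding exactly; round trips are
tested across generated networks with up to 30 taxa and 8 reticulations.

## Simulators

`random_tree()` grows a tree from a single root edge, attaching each new
leaf to a uniformly chosen edge.  Two attachment rules are provided, with
units being edges of the current tree:

* `attach = "edge"` (default): all edges, root edge included.  This
  samples leaf-labelled topologies uniformly (each tree on `i` taxa has
  `2i - 1` insertion slots), which is the natural reading of growth by
  uniform edge subdivision; on three taxa the three topologies appear
  with frequency 1/3 each.
* `attach = "pendant"`: pendant edges only, a Yule-type process giving
  more balanced shapes.

Branch lengths are uniform on (0, 1).  `random_spr()` applies successive
prune-and-regraft moves, excluding regrafts onto the merged edge so that
no move is a topological no-op.  `enumerate_trees()` and
`enumerate_ltsv()` materialize the full spaces for up to 8 taxa
(`(2n-3)!!` objects).  `random_tree_child_network()` adds reticulations to
a random tree by rejection sampling, validating acyclicity and the
tree-child condition.  All simulators take integer seeds and run on a
private RNG stream, restoring the caller's state.

## The benchmark drivers and their conditions

`bench_neighbourhood(n_trees, n_taxa, seed)` reports the distribution of
HOP neighbourhood sizes over random trees.  Its defaults encode the
conditions of the neighbourhood experiment this package reproduces:
pendant attachment, and a single taxon order for all trees taken from the
*first* tree's insertion-order post-order traversal.  These conditions
were fixed by matching the experiment's full reported summary (mean,
standard deviation, minimum and maximum jointly): uniform-edge trees or
per-tree orders produce summaries far from all four values, while the
reconstructed conditions match the spread and the extremes — the minimum
being the first tree encoded under its own traversal order.  Two caveats
belong here rather than in the code: the run-to-run standard deviation of
the 1000-tree mean is about 33 (dominated by the single shared-order
draw), and a residual systematic offset of under 1% from the reported
mean remains, so reproduction of that mean should be judged at the scale
of those run-to-run fluctuations.  `order_mode = "per_tree"` switches to
each tree's own canonical post-order.

`bench_spr_correlation()` generates 50 focal 100-taxon trees, derives 20
trees from each by 5, 10, ..., 100 random SPR moves, and computes the
normalized Robinson-Foulds distance (clade symmetric difference over
`2n = 200`) and the normalized HOP distance (over `n = 100`) under 10
random taxon orders shared across pairs.  Cumulative Pearson correlations
between the SPR count and each distance are reported for pairs with at
most `k` moves, `k = 10, ..., 100`.  At these sizes the whole driver runs
in a few minutes on one core; the per-pair table is returned so that all
correlations can be recomputed from the emitted CSV.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to keep the default run within
minutes while still exercising the reference problem scales: exhaustive spaces at
4–5 taxa (15 and 105 trees) for bijection, metric and connectivity
oracles; 1000 random LCS instances against a quadratic dynamic-programming
oracle; the full 1000-tree neighbourhood experiment; and the full 50-focal
correlation sweep.  What passing these tests shows — and does not show —
about real data: the simulators emulate topology-level processes only
(uniform or Yule shape laws, uniform branch lengths, label-independent
SPR walks); they do not emulate alignment error, rate heterogeneity, or
any sequence-level signal, so the benchmark correlations characterize the
distance's behaviour on synthetic walks through tree space, not its
behaviour on trees estimated from molecular data.

Known limitations: the disk format here is this package's own plain-text
dialect (one header, one taxa line, one body line); its byte size is
within ~20% of Newick's rather than below it, since `2n` integer tokens
outweigh `n` leaf labels plus brackets.  eNewick support covers the
structure needed for tree-child networks (hybrid tags, no branch lengths).
Unrooted trees are not modelled; a tree can be rooted at a designated leaf
upstream if needed.
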