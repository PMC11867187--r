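# ltsvtree

Phylogenetic trees are usually stored and compared through the Newick
format and rearrangement-based distances (NNI, SPR) that are expensive or
intractable to compute.  `ltsvtree` implements an alternative: once the
taxa are indexed `1..n`, every rooted binary tree corresponds to exactly
one integer vector of length `2n` (its **LTSv representation**), obtained
by labelling the internal nodes with taxa and concatenating the resulting
lineage taxon sequences.  Encoding and decoding both run in linear time,
and the correspondence is a bijection.

On these vectors the package provides the **HOP rearrangement**: moving
the first occurrence of taxon *i* to any position after the start and not
beyond the second occurrence of *i − 1*.  Every HOP is a special SPR, the
HOP graph on tree space is connected with Θ(n²) neighbourhoods, and —
unlike NNI or SPR — the HOP distance is computable in near-linear time:

> d_HOP(u, v) = n − Sim_HOP(u, v),
> Sim_HOP(u, v) = Σᵢ |LCS(uᵢ, vᵢ)|

where the uᵢ are the blocks of the canonical decomposition (the vector
cut just before each second occurrence) and each block-wise longest
common subsequence is computed by patience sorting on partial
permutations in O(m log m).  The block-wise LCS additionally yields the
**common forest** — the subtrees shared by both trees — and an explicit
shortest sequence of HOP moves between any two trees.  Extensions cover
annotated vectors (node names, branch lengths), multifurcating trees
(brace-group tokens of length 2n + 2t), and binary tree-child
phylogenetic networks (taxa occurring three times mark reticulations).

For whom: anyone comparing large collections of rooted trees (posterior
samples, bootstrap replicates, competing inferences) who needs a fast,
interpretable dissimilarity with an explicit edit path and shared
structure, or a compact flat representation of trees for downstream
vector-based methods.

## Worked example

```r
library(ltsvtree)

tr  <- parse_newick("((t1,t2),(t3,(t4,t5)));")
ord <- taxon_order(paste0("t", 1:5))
v   <- encode_tree(tr, ord)
v
#> ltsv (n = 5): (1,3,2,1_,2_,4,3_,5,4_,5_)

u <- encode_tree(parse_newick("((t1,(t2,t3)),(t4,t5));"), ord)
hop_similarity(v, u)
#> [1] 3
hop_distance(v, u)
#> [1] 2

common_forest(v, u, ord)
#> common_forest: LCS vector (1,2,1_,2_,3_,5,4_,5_)
#> 3 components: (t1,t2); (t3); (t4,t5);

hop_path(v, u)
#>   taxon target
#> 1     4      2
#> 2     3      5
```

Reading the output: the two trees differ by two HOP moves (the distance),
their vectors share three of five block tokens (the similarity), and the
forest shows what the trees agree on — the cherry `(t1,t2)`, the cherry
`(t4,t5)`, and the isolated leaf `t3`.  The two listed moves transform
`v` into `u` when applied with `apply_hop()`.

A command-line front end over the same functions lives in
`inst/cli/ltsvtree.R` (subcommands `encode`, `decode`, `validate`,
`dist`, `path`, `neighbourhood`, `simulate`, `bench`):

```sh
Rscript inst/cli/ltsvtree.R dist --metric hop --t1 a.nwk --t2 b.nwk
```

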