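Package: ltsvtree
Title: Vector Encoding of Rooted Phylogenetic Trees and the HOP Rearrangement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes rooted phylogenetic trees as integer vectors (the LTSv
    representation), in bijection with leaf-labelled binary tree topologies
    under a fixed taxon order, with linear-time encoding and decoding. Provides
    the HOP tree rearrangement operator defined on these vectors, its
    quadratic-size neighbourhood, and the HOP distance, a tree metric computed
    in near-linear time through longest common subsequences of partial
    permutations, together with shortest HOP paths and the common forest shared
    by two trees. Extensions cover annotated vectors carrying node names and
    branch lengths, multifurcating trees, and binary tree-child phylogenetic
    networks. Includes simulators for random trees, random subtree prune and
    regraft (SPR) walks and random tree-child networks, exhaustive enumeration
    of small tree spaces, and benchmark drivers relating the HOP distance to
    the Robinson-Foulds distance and to SPR walk lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
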