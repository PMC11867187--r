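#' Internal node labelling for the tree encoding
#'
#' For a binary tree on `n` indexed taxa, each non-leaf node receives a
#' unique taxon label: the root gets `1`; a node `x` with children `x1`,
#' `x2` such that `min(x1) > min(x2)` (where `min(u)` is the smallest taxon
#' index below `u`) gets `min(x1)`, the larger of the two child minima.
#' This labelling is a bijection between the `n` non-leaf nodes and the
#' taxa; it defines the decomposition of the tree into the paths `P_i`
#' running from the node labelled `i` down to leaf `i`.
#'
#' @param tree a binary [rooted_tree].
#' @param order a [taxon_order] covering the tree's taxa.
#' @return A list with integer vectors `label` and `minmap`, indexed by node
#'   id (`NA` on leaves/unused slots).
#' @export
label_internal_nodes <- function(tree, order) {
  validate_rooted_tree(tree, binary = TRUE)
  info <- label_nodes_general(tree, order, allow_polytomy = FALSE)
  list(label = info$single_label, minmap = info$minmap)
}

# Shared labelling machinery for the binary and multifurcating encoders.
# Returns per-node: minmap, label_set (list; length 1 for binary nodes and
# the root, k-1 labels for an outdegree-k polytomy), single_label (NA where
# the set has length != 1).
label_nodes_general <- function(tree, order, allow_polytomy = TRUE) {
  idx <- leaf_index_map(tree, order)
  nslot <- length(tree$parent)
  minmap <- rep(NA_integer_, nslot)
  label_set <- vector("list", nslot)
  po <- postorder_nodes(tree)
  for (v in po) {
    if (!is.na(tree$leaf_label[v])) {
      minmap[v] <- idx[[as.character(v)]]
    } else {
      kids <- tree$children[[v]]
      mins <- minmap[kids]
      minmap[v] <- min(mins)
      if (length(kids) == 1L) {
        # degree-1 root handled after the loop
      } else if (length(kids) == 2L) {
        label_set[[v]] <- max(mins)
      } else {
        if (!allow_polytomy)
          stop("node ", v, " has outdegree ", length(kids),
               "; use the multifurcating encoder")
        label_set[[v]] <- sort(mins[-which.min(mins)])
      }
    }
  }
  label_set[[tree$root]] <- minmap[tree$root]
  single <- rep(NA_integer_, nslot)
  for (v in which(lengths(label_set) == 1L))
    single[v] <- label_set[[v]]
  list(minmap = minmap, label_set = label_set, single_label = single,
       leaf_index = idx)
}

#' Encode a binary tree as an LTSv vector
#'
#' Labels the non-leaf nodes (see [label_internal_nodes()]), decomposes the
#' tree into the paths `P_i` from the node labelled `i` to leaf `i`, and
#' concatenates the lineage taxon sequences: the result is
#' `v(P_1) + (1_) + v(P_2) + (2_) + ... + v(P_n) + (n_)`, where `v(P_i)`
#' lists the labels of the nodes of `P_i` strictly below its start node,
#' and `v(P_1)` is additionally prepended with the root's own label `1`.
#' Runs in linear time: each path is found by walking up from its leaf.
#'
#' @param tree a binary [rooted_tree].
#' @param order a [taxon_order]; defaults to the tree's leaf labels sorted
#'   naturally.
#' @return An [ltsv] vector.
#' @examples
#' encode_tree(parse_newick("((1,2),(3,4));"), taxon_order(as.character(1:4)))
#' @export
encode_tree <- function(tree, order = default_order(tree)) {
  lab <- label_internal_nodes(tree, order)
  build_vector_from_labels(tree, lab$label, n_taxa(tree), order)
}

default_order <- function(tree) {
  labs <- tree$leaf_label[tree_leaves(tree)]
  taxon_order(labs[order(natural_sort_key(labs), method = "radix")])
}

# Assemble the token sequence from a single-label map (binary case).
build_vector_from_labels <- function(tree, label, n, order) {
  idx <- leaf_index_map(tree, order)
  leaf_of <- integer(n)
  leaf_of[idx] <- as.integer(names(idx))
  start_of <- integer(n)                 # node labelled i
  nodes <- tree_nodes(tree)
  for (v in nodes) if (!is.na(label[v])) start_of[label[v]] <- v
  tokens <- integer(2L * n)
  pos <- 1L
  for (i in seq_len(n)) {
    path <- integer(0)                   # nodes strictly below start, walking up
    v <- tree$parent[leaf_of[i]]
    while (v != start_of[i]) {
      path <- c(path, v)
      v <- tree$parent[v]
    }
    lts <- rev(label[path])
    if (i == 1L) lts <- c(label[start_of[1L]], lts)
    k <- length(lts)
    if (k) {
      tokens[pos:(pos + k - 1L)] <- lts
      pos <- pos + k
    }
    tokens[pos] <- i
    pos <- pos + 1L
  }
  ltsv(tokens)
}

#' Decode an LTSv vector into a tree
#'
#' Scans adjacent token pairs `(v_j, v_{j+1})` for `j = 1..2n-1`, emitting
#' exactly one edge per pair based on the occurrence pattern (first/second):
#' `(1,1) -> (n+v_j, n+v_{j+1})`, `(1,2) -> (n+v_j, v_{j+1})`,
#' `(2,1) -> (n+(v_j+1), n+v_{j+1})`, `(2,2) -> (n+v_{j+1}, v_{j+1})`.
#' Leaf `i` is node `i` and the non-leaf node corresponding to the first
#' occurrence of `i` is node `n + i`; node `n + 1` is the degree-1 root.
#'
#' @param v an [ltsv] vector.
#' @param order optional [taxon_order] giving the leaf labels; defaults to
#'   `"1" .. "n"`.
#' @return A [rooted_tree] with `2n` nodes and `2n - 1` edges; the edge list
#'   in scan order is attached as the integer matrix attribute `"edges"`
#'   (columns: parent, child).
#' @examples
#' decode_tree(ltsv(c(1, 3, 2, 1, 2, 5, 4, 3, 4, 5)))
#' @export
decode_tree <- function(v, order = NULL) {
  if (!is_ltsv(v)) v <- ltsv(v)
  edges <- decode_edges(v)
  n <- length(unclass(v)) %/% 2L
  if (is.null(order)) order <- taxon_order(as.character(seq_len(n)))
  if (length(order) != n) stop("taxon order length must equal n")
  parent <- rep(NA_integer_, 2L * n)
  leaf_label <- rep(NA_character_, 2L * n)
  leaf_label[seq_len(n)] <- as.character(order)
  for (e in seq_len(nrow(edges))) parent[edges[e, 2L]] <- edges[e, 1L]
  tr <- rooted_tree(parent, leaf_label)
  attr(tr, "edges") <- edges
  tr
}

#' @rdname decode_tree
#' @export
decode_edges <- function(v) {
  if (!is_ltsv(v)) v <- ltsv(v)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  sec <- second_occurrence_flags(tokens)
  if (n == 1L)
    return(matrix(c(2L, 1L), 1L, 2L, dimnames = list(NULL,
                                                     c("parent", "child"))))
  m <- 2L * n - 1L
  from <- integer(m); to <- integer(m)
  for (j in seq_len(m)) {
    a <- tokens[j]; b <- tokens[j + 1L]
    if (!sec[j] && !sec[j + 1L]) { from[j] <- n + a; to[j] <- n + b }
    else if (!sec[j] && sec[j + 1L]) { from[j] <- n + a; to[j] <- b }
    else if (sec[j] && !sec[j + 1L]) { from[j] <- n + a + 1L; to[j] <- n + b }
    else { from[j] <- n + b; to[j] <- b }
  }
  matrix(c(from, to), ncol = 2L, dimnames = list(NULL, c("parent", "child")))
}

# --- annotated encoding ----------------------------------------------------

#' Annotated encoding: vectors carrying node names and branch lengths
#'
#' Every token position corresponds to a node of the tree (first occurrences
#' to non-leaf nodes, second occurrences to leaves), so the vector can carry
#' the full tree: each entry becomes a triplet `index:name:length` where
#' `name` is the node's name (the taxon label for leaves) and `length` the
#' length of the branch entering it.  The name of the very first entry (the
#' root, which has no entering branch) is empty.  The taxon order can be
#' read back from the leaf names, so `decode_tree_annotated()` needs no
#' extra input.
#'
#' @param tree a binary [rooted_tree].
#' @param order a [taxon_order].
#' @return `encode_tree_annotated()`: list with `vector` ([ltsv]), `name`
#'   and `length` (per token position) and `order`.
#' @export
encode_tree_annotated <- function(tree, order = default_order(tree)) {
  lab <- label_internal_nodes(tree, order)
  v <- build_vector_from_labels(tree, lab$label, n_taxa(tree), order)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  sec <- second_occurrence_flags(tokens)
  start_of <- integer(n)
  for (nd in tree_nodes(tree))
    if (!is.na(lab$label[nd])) start_of[lab$label[nd]] <- nd
  idx <- leaf_index_map(tree, order)
  leaf_of <- integer(n); leaf_of[idx] <- as.integer(names(idx))
  node_at <- ifelse(sec, leaf_of[tokens], start_of[tokens])
  name <- ifelse(sec, tree$leaf_label[node_at], tree$node_name[node_at])
  name[1L] <- NA_character_
  len <- tree$edge_length[node_at]
  len[1L] <- NA_real_
  list(vector = v, name = name, length = len, order = order)
}

#' @rdname encode_tree_annotated
#' @param x a list as returned by `encode_tree_annotated()` or
#'   [parse_ltsv()] on an annotated file.
#' @return `decode_tree_annotated()`: a [rooted_tree] with names and branch
#'   lengths restored.
#' @export
decode_tree_annotated <- function(x) {
  v <- x$vector
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  sec <- second_occurrence_flags(tokens)
  order <- if (!is.null(x$order)) taxon_order(x$order) else {
    leaf_names <- character(n)
    leaf_names[tokens[sec]] <- x$name[sec]
    taxon_order(leaf_names)
  }
  tr <- decode_tree(v, order)
  if (!is.null(x$name) || !is.null(x$length)) {
    node_at <- ifelse(sec, tokens, n + tokens)
    if (!is.null(x$name)) {
      nm <- x$name
      tr$node_name[node_at[!sec]] <- nm[!sec]
    }
    if (!is.null(x$length)) tr$edge_length[node_at] <- x$length
  }
  tr
}

# --- multifurcating trees --------------------------------------------------

#' Vector encoding of multifurcating trees
#'
#' Binary nodes are labelled as in [encode_tree()]; a polytomy node with
#' children `u_1, ..., u_k` (`k > 2`) is labelled with the set of all child
#' minima except the smallest, and contributes a single brace-group token.
#' The element count of the result is `2n + 2t` for `t` polytomy nodes,
#' counting each brace-group as its members plus the two braces.  Binary
#' input reproduces [encode_tree()] exactly.
#'
#' A `multi_ltsv` is a list of elements, each a list with `type`
#' (`"first"`, `"second"` or `"group"`) and `taxa` (integer vector, length
#' one unless a group).
#'
#' @param tree a [rooted_tree] with arbitrary outdegrees (>= 2 below the
#'   root).
#' @param order a [taxon_order].
#' @return A `multi_ltsv` object.
#' @examples
#' format(encode_multifurcating(parse_newick("(1,(2,3,4));")))
#' @export
encode_multifurcating <- function(tree, order = default_order(tree)) {
  validate_rooted_tree(tree)
  info <- label_nodes_general(tree, order, allow_polytomy = TRUE)
  n <- n_taxa(tree)
  idx <- info$leaf_index
  leaf_of <- integer(n); leaf_of[idx] <- as.integer(names(idx))
  start_of <- integer(n)                 # node whose label set contains i
  nodes <- tree_nodes(tree)
  for (v in nodes) for (lb in info$label_set[[v]]) start_of[lb] <- v
  elements <- list()
  emitted_at <- rep(FALSE, length(tree$parent))
  push_node <- function(v) {
    ls <- info$label_set[[v]]
    type <- if (length(ls) > 1L) "group" else "first"
    elements[[length(elements) + 1L]] <<- list(type = type,
                                               taxa = as.integer(ls))
  }
  for (i in seq_len(n)) {
    path <- integer(0)
    v <- tree$parent[leaf_of[i]]
    while (v != start_of[i]) {
      path <- c(path, v)
      v <- tree$parent[v]
    }
    if (i == 1L) path <- c(path, start_of[1L])
    for (v in rev(path)) push_node(v)
    elements[[length(elements) + 1L]] <- list(type = "second",
                                              taxa = i)
  }
  structure(list(n = n, elements = elements), class = "multi_ltsv")
}

#' @rdname encode_multifurcating
#' @param x a `multi_ltsv`.
#' @param ... unused.
#' @export
format.multi_ltsv <- function(x, ...) {
  parts <- vapply(x$elements, function(e) {
    if (e$type == "group") paste0("{", paste(e$taxa, collapse = " "), "}")
    else if (e$type == "second") paste0(e$taxa, "_")
    else as.character(e$taxa)
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' @export
print.multi_ltsv <- function(x, ...) {
  cat("multi_ltsv (n = ", x$n, "): ", format(x), "\n", sep = "")
  invisible(x)
}

#' @rdname encode_multifurcating
#' @export
multi_ltsv_length <- function(x) {
  # element count where a brace-group counts its members plus the braces
  sum(vapply(x$elements, function(e)
    if (e$type == "group") length(e$taxa) + 2L else 1L, integer(1)))
}

# Validate the Definition-3.1 conditions reading group members as first
# occurrences; returns the flat token expansion with element indices.
validate_multi_ltsv <- function(x) {
  stopifnot(inherits(x, "multi_ltsv"))
  n <- x$n
  firsts <- integer(0); first_elem <- integer(0)
  seconds <- integer(0)
  for (ei in seq_along(x$elements)) {
    e <- x$elements[[ei]]
    if (e$type == "second") {
      seconds <- c(seconds, e$taxa)
    } else {
      if (e$type == "group" && length(e$taxa) < 2L)
        stop("brace-group must contain at least 2 taxa")
      firsts <- c(firsts, e$taxa)
      first_elem <- c(first_elem, rep(ei, length(e$taxa)))
    }
  }
  if (!identical(sort(firsts), seq_len(n)) ||
      !identical(sort(seconds), seq_len(n)))
    stop("each taxon must occur exactly once as a first and once as a ",
         "second occurrence")
  if (!identical(seconds, seq_len(n)))
    stop("second occurrences must appear in increasing order")
  e1 <- x$elements[[1L]]
  if (e1$type == "second" || e1$taxa[1L] != 1L)
    stop("the vector must start with the first occurrence of taxon 1")
  # condition (iii): first occurrence of i before (i-1)_
  sec_elem <- integer(n)
  for (ei in seq_along(x$elements))
    if (x$elements[[ei]]$type == "second")
      sec_elem[x$elements[[ei]]$taxa] <- ei
  felem <- integer(n); felem[firsts] <- first_elem
  if (n >= 2L) for (i in 2:n)
    if (felem[i] > sec_elem[i - 1L])
      stop("first occurrence of ", i, " appears after the second ",
           "occurrence of ", i - 1L)
  invisible(x)
}

#' @rdname encode_multifurcating
#' @param v a `multi_ltsv`.
#' @return `decode_multifurcating()`: a [rooted_tree]; a brace-group of
#'   size `k - 1` reconstitutes a node of outdegree `k`.
#' @export
decode_multifurcating <- function(v, order = NULL) {
  validate_multi_ltsv(v)
  n <- v$n
  if (is.null(order)) order <- taxon_order(as.character(seq_len(n)))
  m <- length(v$elements)
  # node id per element: leaves are 1..n, first-occurrence elements get ids
  # n + (smallest taxon of the element)
  node_of <- integer(m)
  owner <- integer(n)      # internal node id owning each taxon's label
  for (ei in seq_len(m)) {
    e <- v$elements[[ei]]
    if (e$type == "second") node_of[ei] <- e$taxa
    else {
      node_of[ei] <- n + min(e$taxa)
      owner[e$taxa] <- n + min(e$taxa)
    }
  }
  parent <- rep(NA_integer_, 2L * n)
  add_edge <- function(a, b) parent[b] <<- a
  for (j in seq_len(m - 1L)) {
    e1 <- v$elements[[j]]; e2 <- v$elements[[j + 1L]]
    if (e1$type != "second" && e2$type != "second")
      add_edge(node_of[j], node_of[j + 1L])
    else if (e1$type != "second" && e2$type == "second")
      add_edge(node_of[j], node_of[j + 1L])
    else if (e1$type == "second" && e2$type != "second")
      add_edge(owner[e1$taxa + 1L], node_of[j + 1L])
    else
      add_edge(owner[e2$taxa], node_of[j + 1L])
  }
  leaf_label <- rep(NA_character_, 2L * n)
  leaf_label[seq_len(n)] <- as.character(order)
  rooted_tree(parent, leaf_label)
}
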