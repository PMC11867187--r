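#' Rooted phylogenetic trees with a degree-1 root
#'
#' The internal tree model follows the convention that a rooted phylogenetic
#' tree carries an extra root node of outdegree 1 and indegree 0; the leaves
#' are bijectively labelled by taxa and every internal node has outdegree at
#' least 2 (exactly 2 for binary trees).  A `rooted_tree` is a list with
#' components
#' \describe{
#'   \item{parent}{integer vector, `parent[i]` is the parent node of node `i`
#'     (`NA` for the root);}
#'   \item{children}{list of integer vectors, ordered children per node;}
#'   \item{leaf_label}{character vector, taxon label for leaves, `NA` for
#'     non-leaf nodes;}
#'   \item{edge_length}{numeric vector, length of the edge entering each node
#'     from its parent (`NA` when absent);}
#'   \item{node_name}{character vector, optional node names (`NA` when
#'     absent);}
#'   \item{root}{the root node id.}
#' }
#' Node ids are integers in `1..length(parent)`; unused ids are permitted
#' (entries `NA`/empty), which lets decoded trees use the fixed id scheme
#' where leaf `i` is node `i` and the non-leaf node created by the first
#' occurrence of `i` is node `n + i`.
#'
#' @param parent integer vector of parent ids (`NA` for the root).
#' @param leaf_label character vector of taxon labels (`NA` for non-leaves).
#' @param edge_length optional numeric vector of entering-edge lengths.
#' @param node_name optional character vector of node names.
#' @return An object of class `rooted_tree`.
#' @export
rooted_tree <- function(parent, leaf_label, edge_length = NULL,
                        node_name = NULL) {
  n_slot <- length(parent)
  if (is.null(edge_length)) edge_length <- rep(NA_real_, n_slot)
  if (is.null(node_name)) node_name <- rep(NA_character_, n_slot)
  stopifnot(length(leaf_label) == n_slot, length(edge_length) == n_slot,
            length(node_name) == n_slot)
  used <- which(!is.na(parent) | seq_len(n_slot) %in% parent[!is.na(parent)] |
                  !is.na(leaf_label))
  children <- vector("list", n_slot)
  for (i in seq_len(n_slot)) children[[i]] <- integer(0)
  for (i in used) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  roots <- used[is.na(parent[used])]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  tr <- structure(list(parent = as.integer(parent), children = children,
                       leaf_label = as.character(leaf_label),
                       edge_length = as.numeric(edge_length),
                       node_name = as.character(node_name),
                       root = as.integer(roots)),
                  class = "rooted_tree")
  validate_rooted_tree(tr)
  tr
}

#' @rdname rooted_tree
#' @param x object to test or validate.
#' @export
is_rooted_tree <- function(x) inherits(x, "rooted_tree")

# Structural checks: single degree-1 root, connectivity, acyclicity, unique
# leaf labels.  Called by the constructor; exported for defensive use.
#' @rdname rooted_tree
#' @param binary if `TRUE`, additionally require every internal node to have
#'   outdegree exactly 2.
#' @export
validate_rooted_tree <- function(x, binary = FALSE) {
  stopifnot(is_rooted_tree(x))
  nodes <- tree_nodes(x)
  if (length(x$children[[x$root]]) != 1L)
    stop("root must have outdegree exactly 1")
  labs <- x$leaf_label[nodes]
  leaves <- nodes[!is.na(labs)]
  if (anyDuplicated(stats::na.omit(labs)))
    stop("duplicate leaf labels")
  for (v in nodes) {
    deg <- length(x$children[[v]])
    if (!is.na(x$leaf_label[v])) {
      if (deg != 0L) stop("labelled leaf ", v, " has children")
    } else if (v != x$root) {
      if (deg < 2L) stop("internal node ", v, " has outdegree ", deg)
      if (binary && deg != 2L)
        stop("node ", v, " has outdegree ", deg, " but a binary tree ",
             "was required")
    }
  }
  # connectivity + acyclicity: walk up from every node must reach the root
  # in < |nodes| steps
  nn <- length(nodes)
  for (v in nodes) {
    u <- v; steps <- 0L
    while (!is.na(x$parent[u])) {
      u <- x$parent[u]; steps <- steps + 1L
      if (steps > nn) stop("cycle detected at node ", v)
    }
    if (u != x$root) stop("node ", v, " is disconnected from the root")
  }
  invisible(x)
}

# Active node ids of a tree (skipping unused slots).
tree_nodes <- function(tr) {
  n_slot <- length(tr$parent)
  present <- !is.na(tr$parent) | !is.na(tr$leaf_label)
  present[tr$root] <- TRUE
  which(present)
}

#' @rdname rooted_tree
#' @export
tree_leaves <- function(x) {
  nodes <- tree_nodes(x)
  nodes[!is.na(x$leaf_label[nodes])]
}

#' @rdname rooted_tree
#' @export
n_taxa <- function(x) length(tree_leaves(x))

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree:", n_taxa(x), "taxa,",
      length(tree_nodes(x)), "nodes\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Taxon orders
#'
#' A taxon order is a bijection between taxon labels and the indices
#' `1..n`; every vector encoding is relative to such an order.  It is
#' represented as a character vector of distinct labels, with the position
#' of a label being its index.
#'
#' @param labels character vector of distinct taxon labels.
#' @return The validated order (character vector of class `taxon_order`).
#' @export
taxon_order <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a taxon order needs at least one taxon")
  if (anyDuplicated(labels)) stop("taxon labels must be distinct")
  structure(labels, class = "taxon_order")
}

# Map the leaves of a tree to indices under an order; errors on taxa that the
# order does not cover.
leaf_index_map <- function(tr, order) {
  leaves <- tree_leaves(tr)
  idx <- match(x = tr$leaf_label[leaves], table = as.character(order))
  if (anyNA(idx))
    stop("taxa not covered by the taxon order: ",
         paste(tr$leaf_label[leaves][is.na(idx)], collapse = ", "))
  stats::setNames(idx, as.character(leaves))
}

#' Read and write rooted trees in Newick format
#'
#' `parse_newick()` reads a rooted Newick string (branch lengths and internal
#' node names supported) into a [rooted_tree]; if the string's root has
#' outdegree 2 or more, an extra degree-1 root is prepended, following the
#' convention used throughout the package.  `write_newick()` is the inverse;
#' the degree-1 root is not emitted as a separate Newick node.  Parsing and
#' formatting are delegated to \pkg{ape}.
#'
#' @param text a Newick string (must end with `;`).
#' @param binary_required error if the tree contains a polytomy.
#' @return `parse_newick()`: a [rooted_tree]. `write_newick()`: a Newick
#'   string.
#' @examples
#' tr <- parse_newick("((1,2),(3,4));")
#' write_newick(tr)
#' @export
parse_newick <- function(text, binary_required = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';'")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("Newick parse error near position ", nchar(text), ": ",
         "ape could not read the string")
  tr <- phylo_to_rooted(phy)
  if (binary_required) validate_rooted_tree(tr, binary = TRUE)
  tr
}

#' @rdname parse_newick
#' @param tree a [rooted_tree].
#' @param digits decimal digits used when formatting branch lengths.
#' @export
write_newick <- function(tree, digits = 2) {
  validate_rooted_tree(tree)
  phy <- rooted_to_phylo(tree)
  if (n_taxa(tree) == 1L) {
    lab <- tree$leaf_label[tree_leaves(tree)]
    len <- tree$edge_length[tree_leaves(tree)]
    inner <- if (is.na(len)) lab else
      paste0(lab, ":", formatC(len, format = "f", digits = digits))
    return(paste0("(", inner, ");"))
  }
  ape::write.tree(phy, digits = as.integer(digits))
}

# --- ape interchange ------------------------------------------------------

# phylo -> rooted_tree, prepending the degree-1 root when needed.
phylo_to_rooted <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  has_len <- !is.null(phy$edge.length)
  n_slot <- ntip + nnode + 1L           # +1 for a possible new root
  parent <- rep(NA_integer_, n_slot)
  leaf_label <- rep(NA_character_, n_slot)
  edge_length <- rep(NA_real_, n_slot)
  node_name <- rep(NA_character_, n_slot)
  leaf_label[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[!nzchar(nl)] <- NA_character_
    node_name[ntip + seq_len(nnode)] <- nl
  }
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2L]] <- phy$edge[e, 1L]
    if (has_len) edge_length[phy$edge[e, 2L]] <- phy$edge.length[e]
  }
  phy_root <- ntip + 1L
  if (sum(phy$edge[, 1L] == phy_root) == 1L) {
    # the string's outermost node already has a single child ("(a);" or
    # "((...));"): it is the degree-1 root
    root <- phy_root
  } else {
    root <- n_slot
    parent[phy_root] <- root
    if (!is.null(phy$root.edge)) edge_length[phy_root] <- phy$root.edge
  }
  rooted_tree(parent, leaf_label, edge_length, node_name)
}

# rooted_tree -> phylo; the degree-1 root is stripped (its child becomes the
# phylo root, the root edge length going to root.edge).
rooted_to_phylo <- function(tr) {
  top <- tr$children[[tr$root]][1L]
  leaves <- tree_leaves(tr)
  ntip <- length(leaves)
  if (ntip == 1L) {
    phy <- list(edge = matrix(c(2L, 1L), 1L, 2L), Nnode = 1L,
                tip.label = tr$leaf_label[leaves])
    class(phy) <- "phylo"
    return(phy)
  }
  nodes <- tree_nodes(tr)
  internal <- setdiff(nodes[is.na(tr$leaf_label[nodes])], tr$root)
  # canonical child order: by smallest descendant taxon label (natural sort)
  key <- canonical_key(tr)
  new_id <- integer(length(tr$parent))
  # tips sorted by canonical key for determinism
  tips_sorted <- leaves[order(key[leaves], method = "radix")]
  new_id[tips_sorted] <- seq_len(ntip)
  # internal nodes numbered in preorder from the stripped root
  inorder <- integer(0)
  stack <- top
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (is.na(tr$leaf_label[v])) {
      inorder <- c(inorder, v)
      kids <- tr$children[[v]]
      kids <- kids[order(key[kids], method = "radix")]
      stack <- c(kids, stack)
    }
  }
  new_id[inorder] <- ntip + seq_along(inorder)
  edges <- NULL
  elens <- numeric(0)
  for (v in c(inorder, leaves)) {
    p <- tr$parent[v]
    if (!is.na(p) && p != tr$root) {
      edges <- rbind(edges, c(new_id[p], new_id[v]))
      elens <- c(elens, tr$edge_length[v])
    }
  }
  ord <- order(edges[, 1L], edges[, 2L])
  phy <- list(edge = edges[ord, , drop = FALSE], Nnode = length(inorder),
              tip.label = tr$leaf_label[tips_sorted])
  if (any(!is.na(elens))) {
    el <- elens[ord]
    el[is.na(el)] <- 0
    phy$edge.length <- el
  }
  nn <- tr$node_name[inorder]
  if (any(!is.na(nn))) {
    nn[is.na(nn)] <- ""
    phy$node.label <- nn
  }
  if (!is.na(tr$edge_length[top])) phy$root.edge <- tr$edge_length[top]
  class(phy) <- "phylo"
  phy
}

# Per-node canonical sort key: the smallest descendant leaf label under
# natural (numeric-suffix aware) ordering, used to canonicalize child order.
canonical_key <- function(tr) {
  nodes <- tree_nodes(tr)
  key <- rep(NA_character_, length(tr$parent))
  labs <- tr$leaf_label
  pad <- natural_sort_key
  po <- postorder_nodes(tr)
  for (v in po) {
    if (!is.na(labs[v])) key[v] <- pad(labs[v])
    else {
      kk <- key[tr$children[[v]]]
      key[v] <- if (length(kk)) min(kk) else ""
    }
  }
  key
}

# Natural-sort key: zero-pad digit runs so "t2" < "t10" lexicographically.
natural_sort_key <- function(s) {
  vapply(s, function(si) {
    m <- gregexpr("\\d+", si, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(si)
    parts <- regmatches(si, list(m))[[1L]]
    lens <- attr(m, "match.length")
    out <- character(0)
    last <- 1L
    for (j in seq_along(m)) {
      out <- c(out, substr(si, last, m[j] - 1L),
               formatC(parts[j], width = 12, flag = "0"))
      last <- m[j] + lens[j]
    }
    paste0(paste(out, collapse = ""), substr(si, last, nchar(si)))
  }, character(1), USE.NAMES = FALSE)
}

# Node ids in post-order (children before parents), honouring stored child
# order.  Iterative, so deep caterpillars do not hit the recursion limit.
postorder_nodes <- function(tr) {
  n_slot <- length(tr$parent)
  st <- integer(n_slot); st[1L] <- tr$root; top <- 1L
  visited <- logical(n_slot)
  res <- integer(n_slot); nres <- 0L
  while (top > 0L) {
    v <- st[top]
    kids <- tr$children[[v]]
    if (!visited[v] && length(kids)) {
      visited[v] <- TRUE
      for (k in rev(kids)) { top <- top + 1L; st[top] <- k }
    } else {
      nres <- nres + 1L; res[nres] <- v
      top <- top - 1L
    }
  }
  res[seq_len(nres)]
}

#' Clades of a rooted tree
#'
#' Returns the non-trivial clusters of a tree: for each internal node `u`
#' below the degree-1 root, the set of taxon indices below `u`, excluding
#' singletons and the full taxon set.
#'
#' @param tree a [rooted_tree].
#' @param order a [taxon_order] covering the tree's taxa.
#' @return A list of strictly increasing integer vectors; the list is
#'   de-duplicated and sorted lexicographically, so it can be compared with
#'   `identical()`.
#' @examples
#' clade_set(parse_newick("((1,2),(3,4));"), taxon_order(as.character(1:4)))
#' @export
clade_set <- function(tree, order) {
  validate_rooted_tree(tree)
  idx <- leaf_index_map(tree, order)
  n <- n_taxa(tree)
  po <- postorder_nodes(tree)
  below <- vector("list", length(tree$parent))
  out <- list()
  for (v in po) {
    if (!is.na(tree$leaf_label[v])) {
      below[[v]] <- idx[[as.character(v)]]
    } else {
      s <- sort(unlist(below[tree$children[[v]]], use.names = FALSE))
      below[[v]] <- s
      if (length(s) > 1L && length(s) < n) out[[length(out) + 1L]] <- s
    }
  }
  keys <- vapply(out, paste, character(1), collapse = ",")
  out <- out[!duplicated(keys)]
  out[order(keys[!duplicated(keys)], method = "radix")]
}

#' Restrict a tree to a taxon subset
#'
#' Induced topology on a subset of taxa with all resulting degree-2 internal
#' nodes suppressed; the degree-1 root is retained.  Branch lengths along
#' suppressed paths are summed.
#'
#' @param tree a [rooted_tree].
#' @param subset non-empty character vector of leaf labels to keep.
#' @return A [rooted_tree] on `subset`.
#' @export
restrict_to_taxa <- function(tree, subset) {
  validate_rooted_tree(tree)
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  leaves <- tree_leaves(tree)
  keep <- leaves[tree$leaf_label[leaves] %in% subset]
  if (length(keep) != length(unique(subset)))
    stop("subset contains taxa not present in the tree")
  po <- postorder_nodes(tree)
  nkeep <- integer(length(tree$parent))   # retained descendants per node
  for (v in po) {
    nkeep[v] <- if (v %in% keep) 1L
    else sum(nkeep[tree$children[[v]]])
  }
  # rebuild top-down keeping nodes with >= 2 retained-children branches,
  # the leaves, and the root
  parent <- rep(NA_integer_, length(tree$parent))
  leaf_label <- rep(NA_character_, length(tree$parent))
  edge_length <- rep(NA_real_, length(tree$parent))
  node_name <- rep(NA_character_, length(tree$parent))
  rec_attach <- function(v, anc, len_acc) {
    # v: current original node; anc: id of nearest retained ancestor in the
    # new tree (NA for none yet); len_acc: accumulated length from anc
    repeat {
      kids <- tree$children[[v]][nkeep[tree$children[[v]]] > 0L]
      lv <- tree$edge_length[v]
      if (v %in% keep) {
        parent[v] <<- anc
        leaf_label[v] <<- tree$leaf_label[v]
        edge_length[v] <<- len_acc
        node_name[v] <<- tree$node_name[v]
        return(invisible())
      }
      if (length(kids) >= 2L || is.na(anc)) {
        parent[v] <<- anc
        edge_length[v] <<- len_acc
        node_name[v] <<- tree$node_name[v]
        for (k in kids)
          rec_attach(k, v, add_len(NA_real_, tree$edge_length[k]))
        return(invisible())
      }
      # degree-2 (or pass-through) node: suppress
      v2 <- kids[1L]
      len_acc <- add_len(len_acc, tree$edge_length[v2])
      v <- v2
    }
  }
  add_len <- function(a, b) {
    if (is.na(a)) return(b)
    if (is.na(b)) return(a)
    a + b
  }
  # start from the root, keeping it as degree-1 root
  rootv <- tree$root
  parent[rootv] <- NA_integer_
  top <- tree$children[[rootv]][nkeep[tree$children[[rootv]]] > 0L]
  rec_attach(top[1L], rootv, tree$edge_length[top[1L]])
  # the recursion above stored parent of root already NA; build object
  rooted_tree(parent, leaf_label, edge_length, node_name)
}

#' Topological tree equality
#'
#' Two rooted trees on the same leaf set are equal iff they have the same
#' set of clusters (for rooted trees, the cluster set determines the
#' leaf-labelled topology, for any outdegrees).  Branch lengths and node
#' names are ignored.
#'
#' @param t1,t2 [rooted_tree] objects with identical leaf label sets.
#' @return `TRUE` or `FALSE`.
#' @export
trees_equal <- function(t1, t2) {
  l1 <- sort(t1$leaf_label[tree_leaves(t1)])
  l2 <- sort(t2$leaf_label[tree_leaves(t2)])
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  identical(cluster_keys(t1), cluster_keys(t2))
}

# All clusters (as sorted label strings), one per non-leaf node except the
# degree-1 root (whose cluster duplicates its child's).
cluster_keys <- function(tr) {
  po <- postorder_nodes(tr)
  below <- vector("list", length(tr$parent))
  keys <- character(0)
  for (v in po) {
    if (!is.na(tr$leaf_label[v])) below[[v]] <- tr$leaf_label[v]
    else {
      s <- sort(unlist(below[tr$children[[v]]], use.names = FALSE))
      below[[v]] <- s
      if (v != tr$root) keys <- c(keys, paste(s, collapse = "\r"))
    }
  }
  sort(keys)
}
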