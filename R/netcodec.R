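#' Binary tree-child phylogenetic networks
#'
#' A rooted binary phylogenetic network is an acyclic digraph with a
#' degree-1 root, leaves bijectively labelled by taxa, tree nodes
#' (indegree 1, outdegree 2) and reticulations (indegree 2, outdegree 1).
#' It is tree-child when every non-leaf node has at least one child that
#' is not a reticulation.  Removing all edges entering reticulations
#' splits a network with `r` reticulations into `r + 1` tree components;
#' the one containing the root is the top component.
#'
#' A `tree_child_network` is a list with `edges` (two-column integer
#' matrix, parent then child), `leaf_label` (character per node id, `NA`
#' on non-leaves) and `root`.
#'
#' @param edges two-column integer matrix of directed edges.
#' @param leaf_label character vector indexed by node id.
#' @return A validated `tree_child_network`.
#' @export
tree_child_network <- function(edges, leaf_label) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  net <- structure(list(edges = edges,
                        leaf_label = as.character(leaf_label)),
                   class = "tree_child_network")
  net$root <- network_root(net)
  validate_tree_child_network(net)
  net
}

network_nodes <- function(net) sort(unique(as.integer(net$edges)))

network_edges <- function(net) net$edges

network_root <- function(net) {
  nodes <- sort(unique(as.integer(net$edges)))
  r <- setdiff(nodes, net$edges[, "to"])
  if (length(r) != 1L) stop("network must have exactly one root")
  r
}

indegrees <- function(net) {
  nodes <- network_nodes(net)
  stats::setNames(tabulate(match(net$edges[, "to"], nodes),
                           nbins = length(nodes)), nodes)
}

outdegrees <- function(net) {
  nodes <- network_nodes(net)
  stats::setNames(tabulate(match(net$edges[, "from"], nodes),
                           nbins = length(nodes)), nodes)
}

#' @rdname tree_child_network
#' @param net a `tree_child_network` (or candidate).
#' @export
reticulations <- function(net) {
  ind <- indegrees(net)
  as.integer(names(ind)[ind == 2L])
}

#' @rdname tree_child_network
#' @export
validate_tree_child_network <- function(net) {
  nodes <- network_nodes(net)
  ind <- indegrees(net); outd <- outdegrees(net)
  root <- net$root
  for (v in nodes) {
    k <- as.character(v)
    i <- ind[[k]]; o <- outd[[k]]
    lab <- net$leaf_label[v]
    if (v == root) {
      if (i != 0L || o != 1L) stop("root must have indegree 0, outdegree 1")
    } else if (!is.na(lab)) {
      if (i != 1L || o != 0L) stop("leaf ", lab, " must have indegree 1, ",
                                   "outdegree 0")
    } else if (i == 1L && o == 2L) {
    } else if (i == 2L && o == 1L) {
    } else {
      stop("node ", v, " has indegree ", i, ", outdegree ", o,
           ": not a valid binary network node")
    }
  }
  labs <- net$leaf_label[nodes]
  if (anyDuplicated(stats::na.omit(labs))) stop("duplicate leaf labels")
  # acyclicity via Kahn's algorithm
  ind2 <- ind
  queue <- names(ind2)[ind2 == 0L]
  seen <- 0L
  adj <- split(net$edges[, "to"], net$edges[, "from"])
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in adj[[v]]) {
      k <- as.character(w)
      ind2[[k]] <- ind2[[k]] - 1L
      if (ind2[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (seen != length(nodes)) stop("network contains a cycle")
  # tree-child condition
  ret <- reticulations(net)
  for (v in nodes) {
    if (!is.na(net$leaf_label[v])) next
    kids <- net$edges[net$edges[, "from"] == v, "to"]
    if (length(kids) && all(kids %in% ret))
      stop("tree-child violation at node ", v,
           ": every child is a reticulation")
  }
  invisible(net)
}

#' @export
print.tree_child_network <- function(x, ...) {
  r <- length(reticulations(x))
  cat("tree_child_network:", sum(!is.na(x$leaf_label[network_nodes(x)])),
      "taxa,", r, if (r == 1L) "reticulation\n" else "reticulations\n")
  cat(write_enewick(x), "\n")
  invisible(x)
}

#' @rdname tree_child_network
#' @param tree a binary [rooted_tree].
#' @export
network_from_tree <- function(tree) {
  validate_rooted_tree(tree, binary = TRUE)
  nodes <- tree_nodes(tree)
  child <- nodes[!is.na(tree$parent[nodes])]
  edges <- cbind(from = tree$parent[child], to = child)
  leaf_label <- tree$leaf_label
  tree_child_network(edges, leaf_label)
}

# Convert an r = 0 network back to a rooted_tree.
network_to_tree <- function(net) {
  if (length(reticulations(net)) != 0L)
    stop("network has reticulations; not a tree")
  nslot <- max(network_nodes(net))
  parent <- rep(NA_integer_, nslot)
  parent[net$edges[, "to"]] <- net$edges[, "from"]
  leaf_label <- rep(NA_character_, nslot)
  leaf_label[seq_along(net$leaf_label)] <- net$leaf_label
  rooted_tree(parent, leaf_label)
}

# Subdivide both picked edges and join by a new reticulation edge a -> b.
add_reticulation <- function(net, e1, e2) {
  maxid <- max(network_nodes(net))
  a <- maxid + 1L; b <- maxid + 2L
  ed <- net$edges
  drop <- c(which(ed[, "from"] == e1[["from"]] & ed[, "to"] == e1[["to"]])[1L],
            which(ed[, "from"] == e2[["from"]] & ed[, "to"] == e2[["to"]])[1L])
  ed <- ed[-drop, , drop = FALSE]
  ed <- rbind(ed,
              c(e1[["from"]], a), c(a, e1[["to"]]),
              c(e2[["from"]], b), c(b, e2[["to"]]),
              c(a, b))
  ll <- c(net$leaf_label, NA_character_, NA_character_)
  tryCatch(tree_child_network(ed, ll), error = function(e) NULL)
}

# --- tree components and encoding -----------------------------------------

# Internal: components, labelling and per-component vectors, shared by
# tree_components() and encode_network().
network_analysis <- function(net, order) {
  validate_tree_child_network(net)
  nodes <- network_nodes(net)
  nslot <- max(nodes)
  ret <- reticulations(net)
  # component membership: drop edges entering reticulations, then each node's
  # component root is found by walking up the remaining (unique) parents
  ed <- net$edges
  keep <- !(ed[, "to"] %in% ret)
  up <- rep(NA_integer_, nslot)
  up[ed[keep, "to"]] <- ed[keep, "from"]
  comp_root_of <- function(v) {
    while (!is.na(up[v])) v <- up[v]
    v
  }
  comp_root <- vapply(nodes, comp_root_of, integer(1))
  roots <- unique(comp_root)                 # network root + reticulations
  comp_of <- stats::setNames(match(comp_root, roots), nodes)
  # taxa per component
  labs <- net$leaf_label
  idx_of_label <- stats::setNames(seq_along(order), as.character(order))
  leaf_nodes <- nodes[!is.na(labs[nodes])]
  if (!all(labs[leaf_nodes] %in% names(idx_of_label)))
    stop("taxa not covered by the taxon order")
  leaf_idx <- rep(NA_integer_, nslot)
  leaf_idx[leaf_nodes] <- idx_of_label[labs[leaf_nodes]]
  comp_taxa <- lapply(seq_along(roots), function(ci)
    sort(leaf_idx[leaf_nodes[comp_of[as.character(leaf_nodes)] == ci]]))
  comp_min <- vapply(comp_taxa, min, integer(1))
  # children within components
  kids_in_comp <- vector("list", nslot)
  for (e in which(keep))
    kids_in_comp[[ed[e, "from"]]] <-
      c(kids_in_comp[[ed[e, "from"]]], ed[e, "to"])
  # per-node label: component roots and reticulation parents get component
  # minima; outdegree-2-in-component nodes get the binary min rule
  label <- rep(NA_integer_, nslot)
  ret_comp <- stats::setNames(comp_of[as.character(ret)], ret)
  for (y in ret) {
    parents <- ed[ed[, "to"] == y, "from"]
    label[parents] <- comp_min[ret_comp[[as.character(y)]]]
  }
  for (ci in seq_along(roots)) label[roots[ci]] <- comp_min[ci]
  # within-component minima (over component taxa only), post-order
  minmap <- rep(NA_integer_, nslot)
  topo <- rev(topological_order(net))
  for (v in topo) {
    if (!is.na(leaf_idx[v])) minmap[v] <- leaf_idx[v]
    else {
      kc <- kids_in_comp[[v]]
      if (length(kc)) minmap[v] <- min(minmap[kc])
    }
  }
  for (v in nodes) {
    kc <- kids_in_comp[[v]]
    if (length(kc) == 2L && is.na(net$leaf_label[v]) && is.na(label[v]))
      label[v] <- max(minmap[kc])
    else if (length(kc) == 2L && !(v %in% roots))
      stop("internal error: outdegree-2 node already labelled")
  }
  # per-component vectors via path decomposition, tracking token node ids
  comp_vec <- vector("list", length(roots))
  comp_tok_node <- vector("list", length(roots))
  parent_in_comp <- up
  for (ci in seq_along(roots)) {
    taxa <- comp_taxa[[ci]]
    leaf_node_of <- rep(NA_integer_, max(taxa))
    for (ln in leaf_nodes[comp_of[as.character(leaf_nodes)] == ci])
      leaf_node_of[leaf_idx[ln]] <- ln
    tokens <- integer(0); tok_node <- integer(0)
    for (s in taxa) {
      # collect the nodes strictly below the start node of P_s, bottom-up;
      # the component-min path additionally includes the root itself
      path <- integer(0)
      v <- parent_in_comp[leaf_node_of[s]]
      if (s == comp_min[ci]) {
        while (v != roots[ci]) {
          path <- c(path, v)
          v <- parent_in_comp[v]
        }
        path <- c(path, roots[ci])
      } else {
        while (is.na(label[v]) || label[v] != s) {
          path <- c(path, v)
          v <- parent_in_comp[v]
          if (is.na(v)) stop("internal error: walked past component root")
        }
      }
      lts <- rev(label[path])
      tokens <- c(tokens, lts, s)
      tok_node <- c(tok_node, rev(path), leaf_node_of[s])
    }
    comp_vec[[ci]] <- tokens
    comp_tok_node[[ci]] <- tok_node
  }
  list(roots = roots, comp_of = comp_of, comp_taxa = comp_taxa,
       comp_min = comp_min, label = label, ret = ret,
       comp_vec = comp_vec, comp_tok_node = comp_tok_node)
}

topological_order <- function(net) {
  nodes <- network_nodes(net)
  ind <- indegrees(net)
  adj <- split(net$edges[, "to"], net$edges[, "from"])
  queue <- as.integer(names(ind)[ind == 0L])
  out <- integer(0)
  ind <- stats::setNames(as.integer(ind), names(ind))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[as.character(v)]]) {
      k <- as.character(w)
      ind[[k]] <- ind[[k]] - 1L
      if (ind[[k]] == 0L) queue <- c(queue, w)
    }
  }
  out
}

# Index components by the second-parent rule; returns a permutation of
# component ids (top component first).
order_components <- function(net, an) {
  roots <- an$roots
  r <- length(roots) - 1L
  top <- an$comp_of[[as.character(net$root)]]
  index <- rep(NA_integer_, length(roots))
  index[top] <- 0L
  # token position of every node in its component vector
  pos_in_comp <- vector("list", length(roots))
  for (ci in seq_along(roots)) {
    p <- an$comp_tok_node[[ci]]
    m <- stats::setNames(seq_along(p), p)
    pos_in_comp[[ci]] <- m[!duplicated(names(m))]
  }
  ed <- net$edges
  while (anyNA(index)) {
    cand <- which(is.na(index))
    info <- list()
    for (ci in cand) {
      y <- roots[ci]                      # a reticulation
      parents <- ed[ed[, "to"] == y, "from"]
      pc <- an$comp_of[as.character(parents)]
      if (anyNA(index[pc])) next          # a parent not yet indexed
      if (pc[1L] == pc[2L]) {
        pp <- pos_in_comp[[pc[1L]]][as.character(parents)]
        second <- parents[which.max(pp)]
      } else {
        second <- parents[which.max(index[pc])]
      }
      sc <- an$comp_of[[as.character(second)]]
      info[[length(info) + 1L]] <-
        c(ci = ci, comp_index = index[sc],
          pos = pos_in_comp[[sc]][[as.character(second)]])
    }
    if (!length(info)) stop("internal error: no component became eligible")
    tab <- do.call(rbind, info)
    tab <- tab[order(tab[, "comp_index"], tab[, "pos"]), , drop = FALSE]
    nxt <- max(index, na.rm = TRUE)
    for (k in seq_len(nrow(tab))) index[tab[k, "ci"]] <- nxt + k
  }
  order(index)
}

#' Tree components of a tree-child network
#'
#' Removes every edge entering a reticulation and returns the resulting
#' `r + 1` tree components, ordered by the encoding's component index (top
#' component first, then by the second-parent rule).
#'
#' @param net a [tree_child_network].
#' @param order a [taxon_order] covering the network's taxa.
#' @return A list; each element has `root` (node id; the network root or a
#'   reticulation), `taxa` (integer indices) and `nodes`.
#' @export
tree_components <- function(net, order = default_network_order(net)) {
  an <- network_analysis(net, order)
  perm <- order_components(net, an)
  lapply(perm, function(ci) {
    nodes <- as.integer(names(an$comp_of)[an$comp_of == ci])
    list(root = an$roots[ci], taxa = an$comp_taxa[[ci]], nodes = nodes)
  })
}

#' @rdname tree_components
#' @export
default_network_order <- function(net) {
  labs <- stats::na.omit(net$leaf_label[network_nodes(net)])
  taxon_order(labs[order(natural_sort_key(labs), method = "radix")])
}

#' Vector encoding of tree-child networks
#'
#' Each tree component is encoded like a binary tree over its own taxa,
#' with the component root and both parents of each reticulation labelled
#' by the smallest taxon of the component hanging below that reticulation;
#' reticulation-parent labels therefore name foreign taxa and appear as
#' extra tokens.  Components are concatenated in index order; the top
#' component keeps its full vector while every reticulation-rooted
#' component drops its leading root label (whose information the two
#' parent labels already carry).  A taxon then occurs three times exactly
#' when it is the minimum of a reticulation component, so the number of
#' thrice-occurring taxa equals `r`; for `r = 0` the result is precisely
#' the plain tree encoding.
#'
#' @param net a [tree_child_network].
#' @param order a [taxon_order].
#' @return An integer vector of class `network_ltsv` with attribute `n`.
#' @export
encode_network <- function(net, order = default_network_order(net)) {
  an <- network_analysis(net, order)
  perm <- order_components(net, an)
  out <- integer(0)
  for (k in seq_along(perm)) {
    vec <- an$comp_vec[[perm[k]]]
    if (k > 1L) vec <- vec[-1L]
    out <- c(out, vec)
  }
  structure(out, class = "network_ltsv", n = length(order))
}

#' @export
print.network_ltsv <- function(x, ...) {
  cat("network_ltsv (n = ", attr(x, "n"), "): (",
      paste(unclass(x), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Decode a tree-child network vector
#'
#' Scans the token sequence, orders taxa by their last occurrence and
#' splits the vector at those positions; each block yields a directed path
#' ending in the block's leaf, headed by a connector node.  Connector
#' nodes named by one earlier token are contracted into their parent (tree
#' case); connectors named by two earlier tokens become reticulations.
#' Taxa must occur exactly two or three times.
#'
#' @param v a `network_ltsv` (or plain integer vector).
#' @param order optional [taxon_order] for leaf labels; defaults to
#'   `"1" .. "n"`.
#' @return A [tree_child_network].
#' @export
decode_network <- function(v, order = NULL) {
  tokens <- as.integer(v)
  taxa <- sort(unique(tokens))
  n <- length(taxa)
  if (!identical(taxa, seq_len(n)))
    stop("tokens must cover 1..n")
  cnt <- tabulate(tokens, nbins = n)
  if (any(cnt < 2L | cnt > 3L))
    stop("each taxon must occur exactly two or three times; taxon ",
         which(cnt < 2L | cnt > 3L)[1L], " occurs ",
         cnt[which(cnt < 2L | cnt > 3L)[1L]], " times")
  if (is.null(order)) order <- taxon_order(as.character(seq_len(n)))
  last_pos <- vapply(seq_len(n), function(i) max(which(tokens == i)),
                     integer(1))
  xs <- order(last_pos)                      # taxa by last occurrence
  cuts <- sort(last_pos)
  if (cuts[n] != length(tokens))
    stop("the final token must be a last occurrence")
  # node ids: leaves 1..n; connector z_i -> n + taxon; y nodes fresh
  z_of <- function(taxon) n + taxon
  next_id <- 2L * n
  edges_from <- integer(0); edges_to <- integer(0)
  add_edge <- function(a, b) {
    edges_from <<- c(edges_from, a); edges_to <<- c(edges_to, b)
  }
  y_of_token <- list()                       # per taxon: y nodes naming it
  lo <- 1L
  for (bi in seq_len(n)) {
    xi <- xs[bi]
    block <- if (cuts[bi] > lo) tokens[lo:(cuts[bi] - 1L)] else integer(0)
    lo <- cuts[bi] + 1L
    if (bi == 1L && length(block) && block[1L] == xi)
      block <- block[-1L]                    # top-component root label
    prev <- z_of(xi)
    for (a in block) {
      next_id <- next_id + 1L
      add_edge(prev, next_id)
      y_of_token[[as.character(a)]] <-
        c(y_of_token[[as.character(a)]], next_id)
      prev <- next_id
    }
    add_edge(prev, xi)                       # leaf
  }
  # connect y nodes to the connectors they name
  for (a in names(y_of_token))
    for (y in y_of_token[[a]]) add_edge(y, z_of(as.integer(a)))
  # contract connectors of twice-occurring taxa (one naming token) into
  # their single parent; the first block's connector (no naming token)
  # stays as the degree-1 root
  for (i in seq_len(n)) {
    z <- z_of(i)
    named_by <- y_of_token[[as.character(i)]]
    if (length(named_by) == 1L) {
      zkid <- edges_to[edges_from == z]
      drop <- which((edges_from == named_by & edges_to == z) |
                      (edges_from == z))
      edges_from <- edges_from[-drop]; edges_to <- edges_to[-drop]
      add_edge(named_by, zkid)
    } else if (length(named_by) > 2L) {
      stop("taxon ", i, " named by more than two tokens")
    }
  }
  leaf_label <- rep(NA_character_, max(c(edges_from, edges_to)))
  leaf_label[seq_len(n)] <- as.character(order)
  tree_child_network(cbind(edges_from, edges_to), leaf_label)
}

#' Network isomorphism under a fixed taxon order
#'
#' Two tree-child networks on the same taxa are compared through their
#' canonical vector encodings under a common taxon order; the encoding
#' determines the network, so equal vectors mean isomorphic networks.
#'
#' @param n1,n2 [tree_child_network]s.
#' @param order a [taxon_order]; defaults to the sorted leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
networks_isomorphic <- function(n1, n2, order = default_network_order(n1)) {
  identical(as.integer(encode_network(n1, order)),
            as.integer(encode_network(n2, order)))
}

# --- extended Newick interchange ------------------------------------------

#' Read and write tree-child networks in extended Newick
#'
#' Reticulations are written with hybrid tags `#H1, #H2, ...`: the subtree
#' below a reticulation appears under one parent, the other parent carries
#' a tagged leaf referencing it.
#'
#' @param net a [tree_child_network].
#' @return `write_enewick()`: a string.  `parse_enewick()`: a
#'   [tree_child_network].
#' @export
write_enewick <- function(net) {
  ret <- reticulations(net)
  tag <- stats::setNames(paste0("#H", seq_along(ret)), ret)
  primary <- stats::setNames(rep(NA_integer_, length(ret)), ret)
  for (y in ret)
    primary[[as.character(y)]] <- net$edges[net$edges[, "to"] == y,
                                            "from"][1L]
  rec <- function(v, from) {
    k <- as.character(v)
    if (v %in% ret) {
      if (from != primary[[k]]) return(tag[[k]])
      kid <- net$edges[net$edges[, "from"] == v, "to"]
      return(paste0("(", rec(kid, v), ")", tag[[k]]))
    }
    lab <- net$leaf_label[v]
    if (!is.na(lab)) return(lab)
    kids <- net$edges[net$edges[, "from"] == v, "to"]
    paste0("(", paste(vapply(kids, rec, character(1), from = v),
                      collapse = ","), ")")
  }
  top <- net$edges[net$edges[, "from"] == net$root, "to"]
  paste0(rec(top, net$root), ";")
}

#' @rdname write_enewick
#' @param text an extended Newick string.
#' @export
parse_enewick <- function(text) {
  s <- gsub("[ \t\n]", "", text)
  if (!endsWith(s, ";")) stop("eNewick parse error: missing ';'")
  s <- substr(s, 1L, nchar(s) - 1L)
  next_id <- 1L
  edges_from <- integer(0); edges_to <- integer(0)
  labels <- character(0)
  new_node <- function(lab = NA_character_) {
    id <- next_id; next_id <<- next_id + 1L
    labels[id] <<- lab
    id
  }
  add_edge <- function(a, b) {
    edges_from <<- c(edges_from, a); edges_to <<- c(edges_to, b)
  }
  pos <- 1L
  peek <- function() substr(s, pos, pos)
  parse_label <- function() {
    start <- pos
    while (pos <= nchar(s) && !(peek() %in% c("(", ")", ",", ":")))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- c(parse_node())
      while (peek() == ",") {
        pos <<- pos + 1L
        kids <- c(kids, parse_node())
      }
      if (peek() != ")") stop("eNewick parse error at position ", pos)
      pos <<- pos + 1L
      lab <- parse_label()
      v <- new_node(if (nzchar(lab)) lab else NA_character_)
      for (kk in kids) add_edge(v, kk)
      v
    } else {
      lab <- parse_label()
      if (!nzchar(lab)) stop("eNewick parse error: empty label at ", pos)
      new_node(lab)
    }
  }
  top <- parse_node()
  if (pos <= nchar(s)) stop("eNewick parse error: trailing characters")
  root <- new_node()
  add_edge(root, top)
  # merge hybrid-tagged nodes: the tagged node with children is the real
  # reticulation; tagged leaves re-route their parent edge to it
  tags <- grep("^#H", labels)
  tagnames <- labels[tags]
  for (tg in unique(tagnames)) {
    ids <- tags[tagnames == tg]
    real <- ids[ids %in% edges_from]
    if (length(real) != 1L)
      stop("eNewick: hybrid tag ", tg, " must subtend exactly one subtree")
    for (ref in setdiff(ids, real))
      edges_to[edges_to == ref] <- real
    labels[real] <- NA_character_
  }
  used <- sort(unique(c(edges_from, edges_to)))
  leaf_label <- rep(NA_character_, max(used))
  is_leaf <- !(used %in% edges_from)
  leaf_label[used[is_leaf]] <- labels[used[is_leaf]]
  tree_child_network(cbind(edges_from, edges_to), leaf_label)
}
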