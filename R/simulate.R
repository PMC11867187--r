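# Seed handling: functions taking a `seed` argument run on a private RNG
# stream and restore the caller's state afterwards, so simulations are
# reproducible without clobbering the session RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Random binary trees by leaf attachment
#'
#' Grows a tree starting from a single edge root--`t1` and adds the
#' remaining leaves one at a time.  With `attach = "edge"` the attachment
#' edge is chosen uniformly among all current edges (the root edge
#' included), which samples leaf-labelled topologies uniformly; with
#' `attach = "pendant"` only pendant (leaf) edges are candidates, giving a
#' Yule-type, more balanced shape distribution.  The chosen edge is
#' subdivided and the new leaf hung from the new node; the new leaf is
#' stored as the first child, so insertion-order traversals (see
#' [taxa_orders()] mode `"postorder_stored"`) visit the youngest subtree
#' first.  Branch lengths are drawn uniformly on (0, 1).
#'
#' @param n number of taxa (>= 1); leaves are labelled `t1 .. tn` by
#'   default.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param labels leaf labels (length `n`).
#' @param branch_lengths draw uniform(0,1) branch lengths.
#' @param attach attachment-edge rule, `"edge"` or `"pendant"`.
#' @return A binary [rooted_tree] on `n` taxa (2n nodes).
#' @export
random_tree <- function(n, seed = NULL, labels = paste0("t", seq_len(n)),
                        branch_lengths = TRUE,
                        attach = c("edge", "pendant")) {
  n <- as.integer(n)
  attach <- match.arg(attach)
  if (n < 1L) stop("n must be at least 1")
  stopifnot(length(labels) == n)
  old <- local_rng(seed)
  on.exit(if (!is.null(seed)) restore_rng(old))
  nslot <- 2L * n
  parent <- rep(NA_integer_, nslot)
  leaf_label <- rep(NA_character_, nslot)
  kids <- vector("list", nslot)
  root <- n + 1L
  parent[1L] <- root
  leaf_label[1L] <- labels[1L]
  kids[[root]] <- 1L
  edge_children <- c(1L)     # edges identified by their child node
  next_internal <- n + 2L
  for (i in seq_len(n - 1L) + 1L) {
    cand <- if (attach == "edge") edge_children
    else edge_children[!is.na(leaf_label[edge_children])]
    e <- cand[sample.int(length(cand), 1L)]
    mid <- next_internal; next_internal <- next_internal + 1L
    p <- parent[e]
    kids[[p]][kids[[p]] == e] <- mid
    parent[mid] <- p
    parent[e] <- mid
    parent[i] <- mid
    kids[[mid]] <- c(i, e)              # new leaf first
    leaf_label[i] <- labels[i]
    edge_children <- c(edge_children, mid, i)
  }
  lens <- rep(NA_real_, nslot)
  if (branch_lengths) {
    nodes <- which(!is.na(parent))
    lens[nodes] <- stats::runif(length(nodes))
  }
  tr <- rooted_tree(parent, leaf_label, lens)
  tr$children <- kids                   # keep insertion order for traversals
  tr
}

#' Random SPR walks
#'
#' Applies `k` successive subtree prune-and-regraft moves.  Each move
#' prunes a uniformly chosen non-root edge (never detaching the whole
#' tree), suppresses the resulting degree-2 node, and regrafts the pruned
#' subtree on a uniformly chosen edge of the remaining tree, excluding the
#' merged edge (which would recreate the original position); the root edge
#' is a legal regraft target.  No move is therefore a topological no-op.
#'
#' @param tree a binary [rooted_tree] with `n >= 3` taxa.
#' @param k number of SPR moves (>= 0).
#' @param seed optional integer seed.
#' @return A binary [rooted_tree] on the same taxa.
#' @export
random_spr <- function(tree, k = 1, seed = NULL) {
  validate_rooted_tree(tree, binary = TRUE)
  if (n_taxa(tree) < 3L) stop("SPR requires at least 3 taxa")
  old <- local_rng(seed)
  on.exit(if (!is.null(seed)) restore_rng(old))
  parent <- tree$parent
  root <- tree$root
  nslot <- length(parent)
  for (step in seq_len(k)) {
    nodes <- which(!is.na(parent))
    top <- nodes[parent[nodes] == root]
    # prune candidates: any non-root edge whose removal leaves >= 2 edges
    subtree_sizes <- rep(1L, nslot)
    # count edges in each subtree by bottom-up accumulation
    ord <- nodes[order(vapply(nodes, function(v) depth_of(parent, v),
                              integer(1)), decreasing = TRUE)]
    sz <- rep(0L, nslot)
    for (v in ord) {
      p <- parent[v]
      szv <- sz[v] + 1L                  # edges in subtree incl. entering edge
      if (!is.na(p)) sz[p] <- sz[p] + szv
    }
    total_edges <- length(nodes)
    cand <- setdiff(nodes, top)
    # after pruning, the two edges at the suppressed node merge into one;
    # at least one non-merged regraft edge must remain
    cand <- cand[total_edges - (sz[cand] + 1L) - 1L >= 2L]
    w <- cand[sample.int(length(cand), 1L)]
    u <- parent[w]                       # suppressed node
    p <- parent[u]
    sib <- other_child(parent, u, w, nodes)
    # detach: merge (p,u)+(u,sib) into (p,sib)
    parent[sib] <- p
    parent[u] <- NA_integer_
    # regraft candidates: edges of remaining tree except merged edge (sib)
    # and except edges inside the pruned subtree
    in_pruned <- subtree_nodes(parent, w, nodes)
    remaining <- setdiff(which(!is.na(parent)), c(in_pruned, sib))
    f <- remaining[sample.int(length(remaining), 1L)]
    parent[u] <- parent[f]
    parent[f] <- u
    parent[w] <- u
  }
  out <- tree
  out$parent <- parent
  out$edge_length <- rep(NA_real_, nslot)   # topology-only result
  rebuild_children(out)
}

depth_of <- function(parent, v) {
  d <- 0L
  while (!is.na(parent[v])) { v <- parent[v]; d <- d + 1L }
  d
}

other_child <- function(parent, u, w, nodes) {
  kids <- nodes[!is.na(parent[nodes]) & parent[nodes] == u]
  kids[kids != w]
}

subtree_nodes <- function(parent, w, nodes) {
  keep <- w
  frontier <- w
  while (length(frontier)) {
    kids <- nodes[!is.na(parent[nodes]) & parent[nodes] %in% frontier]
    frontier <- setdiff(kids, keep)
    keep <- c(keep, frontier)
  }
  keep
}

rebuild_children <- function(tr) {
  rooted_tree(tr$parent, tr$leaf_label, tr$edge_length, tr$node_name)
}

#' Taxon orders from trees
#'
#' `mode = "postorder"` returns the leaf sequence of a post-order traversal
#' with children visited in canonical order (by smallest descendant label);
#' `"postorder_stored"` traverses children in stored order instead (for
#' trees built by [random_tree()] this is insertion order, youngest subtree
#' first); `"alphabetical"` sorts labels naturally (so `t2` precedes
#' `t10`); `"random"` draws a uniform permutation.
#'
#' @param tree a [rooted_tree].
#' @param mode `"postorder"`, `"postorder_stored"`, `"alphabetical"` or
#'   `"random"`.
#' @param seed optional integer seed (random mode).
#' @return A [taxon_order].
#' @export
taxa_orders <- function(tree, mode = c("postorder", "postorder_stored",
                                       "alphabetical", "random"),
                        seed = NULL) {
  mode <- match.arg(mode)
  labs <- tree$leaf_label[tree_leaves(tree)]
  if (mode == "alphabetical")
    return(taxon_order(labs[order(natural_sort_key(labs),
                                  method = "radix")]))
  if (mode == "random") {
    old <- local_rng(seed)
    on.exit(if (!is.null(seed)) restore_rng(old))
    return(taxon_order(sample(labs)))
  }
  key <- if (mode == "postorder") canonical_key(tree) else NULL
  out <- character(0)
  visited <- logical(length(tree$parent))
  st <- c(tree$root)
  while (length(st)) {
    v <- st[length(st)]
    kids <- tree$children[[v]]
    if (!is.null(key) && length(kids))
      kids <- kids[order(key[kids], method = "radix")]
    if (!visited[v] && length(kids)) {
      visited[v] <- TRUE
      st <- c(st, rev(kids))
    } else {
      if (!is.na(tree$leaf_label[v])) out <- c(out, tree$leaf_label[v])
      st <- st[-length(st)]
    }
  }
  taxon_order(out)
}

#' Enumerate all rooted binary trees on small taxon sets
#'
#' Builds every leaf-labelled rooted binary topology on taxa `1..n` by the
#' standard leaf-insertion recursion: the tree on one taxon is a single
#' edge, and each tree on `i` taxa yields `2i - 1` trees on `i + 1` taxa by
#' subdividing each of its edges.  There are `(2n - 3)!!` such trees.
#'
#' @param n number of taxa, at most 8 (the count grows as `(2n-3)!!`).
#' @return A list of [rooted_tree]s with leaf labels `"1" .. "n"`.
#' @export
enumerate_trees <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (n > 8L) stop("n > 8 would enumerate ", prod(seq(1, 2 * n - 3, 2)),
                   " trees; refusing")
  nslot <- 2L * n
  base <- rep(NA_integer_, nslot)
  base[1L] <- n + 1L
  trees <- list(base)   # parent vectors; root is n+1; leaf i at slot i
  if (n >= 2L) for (i in 2:n) {
    nxt <- list()
    mid <- n + i
    for (pv in trees) {
      edges <- which(!is.na(pv))
      for (e in edges) {
        pv2 <- pv
        pv2[mid] <- pv2[e]
        pv2[e] <- mid
        pv2[i] <- mid
        nxt[[length(nxt) + 1L]] <- pv2
      }
    }
    trees <- nxt
  }
  leaf_label <- rep(NA_character_, nslot)
  leaf_label[seq_len(n)] <- as.character(seq_len(n))
  lapply(trees, function(pv) rooted_tree(pv, leaf_label))
}

#' Enumerate all LTSv vectors on n taxa
#'
#' Backtracking enumeration of every length-`2n` sequence satisfying the
#' four tree-representation conditions; there are `(2n - 3)!!` of them,
#' one per binary tree topology.
#'
#' @param n number of taxa, at most 8.
#' @return A list of [ltsv] vectors.
#' @export
enumerate_ltsv <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (n > 8L) stop("n too large for exhaustive enumeration")
  out <- list()
  tokens <- integer(2L * n)
  rec <- function(pos, used_first, next_second) {
    if (pos > 2L * n) {
      out[[length(out) + 1L]] <<- ltsv(tokens)
      return(invisible())
    }
    # place the next second occurrence here?
    if (next_second <= n && used_first[next_second]) {
      tokens[pos] <<- next_second
      rec(pos + 1L, used_first, next_second + 1L)
    }
    # or any unused first occurrence i, subject to (ii) and (iii):
    # i's first occurrence must precede (i-1)_, i.e. i - 1 >= next_second
    for (i in which(!used_first)) {
      if (pos == 1L && i != 1L) next
      if (i > 1L && (i - 1L) < next_second) next
      uf <- used_first; uf[i] <- TRUE
      tokens[pos] <<- i
      rec(pos + 1L, uf, next_second)
    }
    invisible()
  }
  rec(1L, logical(n), 1L)
  out
}

#' Random tree-child networks
#'
#' Grows a random binary tree and adds `r` reticulations by repeatedly
#' picking two distinct edges, subdividing both, and joining the new nodes
#' by a reticulation edge; proposals creating a cycle or violating the
#' tree-child condition are rejected and resampled (bounded retries).
#'
#' @param n number of taxa.
#' @param r number of reticulations, `0 <= r <= n - 1`.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling budget per reticulation.
#' @return A [tree_child_network].
#' @export
random_tree_child_network <- function(n, r = 0, seed = NULL,
                                      max_tries = 200) {
  n <- as.integer(n); r <- as.integer(r)
  if (r > n - 1L) stop("tree-child feasibility requires r <= n - 1")
  old <- local_rng(seed)
  on.exit(if (!is.null(seed)) restore_rng(old))
  tr <- random_tree(n, branch_lengths = FALSE)
  net <- network_from_tree(tr)
  for (step in seq_len(r)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- propose_reticulation(net)
      if (!is.null(cand)) { net <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not place reticulation ", step, " after ",
                  max_tries, " tries (n = ", n, ", r = ", r, ")")
  }
  net
}

# One rejection-sampling proposal; returns NULL when rejected.
propose_reticulation <- function(net) {
  edges <- network_edges(net)
  m <- nrow(edges)
  i <- sample.int(m, 1L); j <- sample.int(m, 1L)
  if (i == j) return(NULL)
  e1 <- edges[i, ]; e2 <- edges[j, ]   # new edge runs e1-node -> e2-node
  cand <- add_reticulation(net, e1, e2)
  if (is.null(cand)) return(NULL)
  ok <- tryCatch({ validate_tree_child_network(cand); TRUE },
                 error = function(e) FALSE)
  if (ok) cand else NULL
}
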