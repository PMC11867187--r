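# Independent oracles used across the suite.  These deliberately avoid the
# package's own fast paths: quadratic DP for LCS, breadth-first search over
# explicitly materialized neighbourhoods for distances, and brute-force
# enumeration for SPR.

# Classic quadratic dynamic-programming LCS length.
dp_lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  d <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L
      else max(d[i, j + 1L], d[i + 1L, j])
  d[na + 1L, nb + 1L]
}

vec_key <- function(v) paste(as.integer(v), collapse = ",")

# Breadth-first shortest path lengths in the HOP graph from a source vector.
bfs_hop_distances <- function(src) {
  dist <- list()
  dist[[vec_key(src)]] <- 0L
  frontier <- list(src)
  while (length(frontier)) {
    nxt <- list()
    for (v in frontier) {
      dv <- dist[[vec_key(v)]]
      for (w in hop_neighbourhood(v)) {
        k <- vec_key(w)
        if (is.null(dist[[k]])) {
          dist[[k]] <- dv + 1L
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# All distinct trees one rooted SPR away from a binary tree, as canonical
# cluster-key strings (brute force over all prune/regraft pairs).
spr_neighbourhood_keys <- function(tree) {
  parent0 <- tree$parent
  root <- tree$root
  nodes <- which(!is.na(parent0))
  keys <- character(0)
  for (w in nodes) {
    if (parent0[w] == root) next
    u <- parent0[w]
    p <- parent0[u]
    kids <- nodes[parent0[nodes] == u]
    sib <- kids[kids != w]
    parent <- parent0
    parent[sib] <- p
    parent[u] <- NA_integer_
    pruned <- w
    frontier <- w
    while (length(frontier)) {
      more <- nodes[!is.na(parent[nodes]) & parent[nodes] %in% frontier]
      frontier <- setdiff(more, pruned)
      pruned <- c(pruned, frontier)
    }
    remaining <- setdiff(which(!is.na(parent)), pruned)
    for (f in remaining) {
      par2 <- parent
      par2[u] <- par2[f]
      par2[f] <- u
      par2[w] <- u
      cand <- rooted_tree(par2, tree$leaf_label)
      keys <- c(keys, paste(ltsvtree:::cluster_keys(cand), collapse = "|"))
    }
  }
  base <- paste(ltsvtree:::cluster_keys(tree), collapse = "|")
  setdiff(unique(keys), base)
}

tree_key <- function(tree) paste(ltsvtree:::cluster_keys(tree), collapse = "|")

# All permutations of a small character vector.
combinat_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
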