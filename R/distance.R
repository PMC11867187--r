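#' Longest common subsequence of two partial permutations
#'
#' A partial permutation is a sequence over the taxa in which no symbol
#' repeats.  The LCS of two partial permutations reduces to a longest
#' increasing subsequence: shared symbols of `a` are mapped to their
#' positions in `b` and an LIS of that mapped sequence is computed by
#' patience sorting in `O(m log m)` (`m` shared symbols).  When a witness is
#' requested, the witness returned is the one occupying the earliest
#' possible positions in `a` (computed greedily from tail LIS lengths),
#' which makes downstream forest construction deterministic.
#'
#' @param a,b integer vectors with no repeated entries (possibly empty).
#' @param witness also return one LCS witness.
#' @return A list with `length`, and when `witness = TRUE` also `witness`
#'   (the common subsequence), `positions_a` and `positions_b` (its
#'   positions in `a` and `b`).
#' @examples
#' lcs_partial_permutation(c(1, 3, 2), c(1, 2, 3), witness = TRUE)
#' @export
lcs_partial_permutation <- function(a, b, witness = FALSE) {
  a <- as.integer(a); b <- as.integer(b)
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("inputs must be partial permutations (no repeated symbol)")
  pos_b <- integer(0)
  if (length(b)) pos_b <- stats::setNames(seq_along(b), b)
  shared_idx <- which(as.character(a) %in% names(pos_b))
  r <- unname(pos_b[as.character(a[shared_idx])])
  m <- length(r)
  if (m == 0L) {
    out <- list(length = 0L)
    if (witness) {
      out$witness <- integer(0)
      out$positions_a <- integer(0)
      out$positions_b <- integer(0)
    }
    return(out)
  }
  if (!witness) return(list(length = lis_length(r)))
  # tail LIS lengths f[i] = longest strictly increasing run starting at i
  f <- integer(m)
  for (i in m:1) {
    best <- 0L
    if (i < m) {
      later <- f[(i + 1L):m][r[(i + 1L):m] > r[i]]
      if (length(later)) best <- max(later)
    }
    f[i] <- best + 1L
  }
  L <- max(f)
  need <- L; last <- -1L
  picks <- integer(0)
  for (i in seq_len(m)) {
    if (r[i] > last && f[i] >= need) {
      picks <- c(picks, i)
      last <- r[i]
      need <- need - 1L
      if (need == 0L) break
    }
  }
  list(length = L,
       witness = a[shared_idx[picks]],
       positions_a = shared_idx[picks],
       positions_b = r[picks])
}

# Patience-sorting LIS length (strictly increasing), O(m log m).
lis_length <- function(r) {
  tails <- integer(0)
  for (x in r) {
    k <- findInterval(x, tails)  # tails is strictly increasing
    if (k == length(tails)) tails <- c(tails, x)
    else tails[k + 1L] <- x
  }
  length(tails)
}

#' HOP similarity and distance
#'
#' The HOP similarity of two LTSv vectors is the sum over the canonical
#' decomposition blocks of the block-wise LCS lengths; it equals `n`
#' exactly when the vectors are equal.  The HOP distance -- the minimum
#' number of HOP moves transforming one vector into the other -- equals
#' `n` minus the similarity, is a metric for a fixed taxon order, and is
#' computed in `O(n log n)` time.
#'
#' @param u,v [ltsv] vectors on the same number of taxa.
#' @return An integer.
#' @examples
#' u <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
#' v <- ltsv(c(1, 2, 3, 1, 4, 2, 3, 4))
#' hop_similarity(u, v)  # 2
#' hop_distance(u, v)    # 2
#' @export
hop_similarity <- function(u, v) {
  if (!is_ltsv(u)) u <- ltsv(u)
  if (!is_ltsv(v)) v <- ltsv(v)
  if (length(u) != length(v))
    stop("vectors have different numbers of taxa")
  bu <- canonical_decomposition(u)
  bv <- canonical_decomposition(v)
  s <- 0L
  for (i in seq_along(bu))
    s <- s + lcs_partial_permutation(bu[[i]], bv[[i]])$length
  s
}

#' @rdname hop_similarity
#' @export
hop_distance <- function(u, v) {
  if (!is_ltsv(u)) u <- ltsv(u)
  if (!is_ltsv(v)) v <- ltsv(v)
  n <- length(unclass(u)) %/% 2L
  if (n == 1L) {
    if (length(u) != length(v)) stop("vectors have different numbers of taxa")
    return(0L)  # a single tree exists on one taxon
  }
  n - hop_similarity(u, v)
}

#' Common forest of two trees
#'
#' Interleaving the block-wise LCS witnesses with all second occurrences
#' `1_..n_` yields a reduced vector that decodes -- by the same
#' path-gluing rules as tree decoding -- into a forest over the taxa whose
#' components appear in both input trees (in the restriction sense: each
#' component equals the restriction of either tree to the component's
#' taxa).  The number of components is `n` minus the number of witness
#' tokens gluing paths together.
#'
#' @param u,v [ltsv] vectors on the same number of taxa.
#' @param order optional [taxon_order] used to label the component leaves;
#'   defaults to `"1" .. "n"`.
#' @return A list of class `common_forest` with `lcs_tokens` (integer
#'   vector), `lcs_second` (logical flags marking second occurrences),
#'   `components` (list of [rooted_tree]s) and `component_taxa` (list of
#'   integer vectors partitioning `1..n`).
#' @examples
#' cf <- common_forest(ltsv(c(1, 3, 2, 1, 2, 4, 3, 4)),
#'                     ltsv(c(1, 2, 3, 1, 4, 2, 3, 4)))
#' length(cf$components)  # 3
#' @export
common_forest <- function(u, v, order = NULL) {
  if (!is_ltsv(u)) u <- ltsv(u)
  if (!is_ltsv(v)) v <- ltsv(v)
  if (length(u) != length(v))
    stop("vectors have different numbers of taxa")
  n <- length(unclass(u)) %/% 2L
  if (is.null(order)) order <- taxon_order(as.character(seq_len(n)))
  bu <- canonical_decomposition(u)
  bv <- canonical_decomposition(v)
  tokens <- integer(0); second <- logical(0)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    w <- if (i <= length(bu))
      lcs_partial_permutation(bu[[i]], bv[[i]], witness = TRUE)$witness
    else integer(0)
    blocks[[i]] <- w
    tokens <- c(tokens, w, i)
    second <- c(second, rep(FALSE, length(w)), TRUE)
  }
  # decode by path gluing: one path per taxon, z-nodes glued where a
  # witness token names the taxon, contracted when unreferenced
  parent <- rep(NA_integer_, 2L * n)
  leaf_label <- rep(NA_character_, 2L * n)
  leaf_label[seq_len(n)] <- as.character(order)
  for (i in seq_len(n)) {
    w <- blocks[[i]]
    if (length(w) && w[1L] == i) w <- w[-1L]  # leading self-label (root)
    prev <- n + i                            # z-node of taxon i
    for (x in w) {
      parent[n + x] <- prev                  # glue: token x names z_x
      prev <- n + x
    }
    parent[i] <- prev
  }
  # z-nodes never referenced by a witness token are either component roots
  # (indegree 0; kept as degree-1 roots) or pass-through: here a z-node
  # always has exactly one child by construction, so each weak component is
  # a rooted tree with a degree-1 root
  comp_roots <- setdiff(n + seq_len(n), which(!is.na(parent)))
  comp_roots <- comp_roots[vapply(comp_roots, function(z)
    any(parent == z, na.rm = TRUE), logical(1))]
  components <- list(); component_taxa <- list()
  for (z in sort(comp_roots)) {
    # collect the subtree below z
    keep <- z
    frontier <- z
    while (length(frontier)) {
      kids <- which(!is.na(parent) & parent %in% frontier)
      keep <- c(keep, kids)
      frontier <- kids
    }
    sub_parent <- rep(NA_integer_, 2L * n)
    sub_parent[setdiff(keep, z)] <- parent[setdiff(keep, z)]
    sub_leaf <- rep(NA_character_, 2L * n)
    taxa <- intersect(keep, seq_len(n))
    sub_leaf[taxa] <- leaf_label[taxa]
    components[[length(components) + 1L]] <-
      rooted_tree(sub_parent, sub_leaf)
    component_taxa[[length(component_taxa) + 1L]] <- sort(taxa)
  }
  structure(list(lcs_tokens = tokens, lcs_second = second,
                 components = components, component_taxa = component_taxa),
            class = "common_forest")
}

#' @export
print.common_forest <- function(x, ...) {
  shown <- ifelse(x$lcs_second, paste0(x$lcs_tokens, "_"), x$lcs_tokens)
  cat("common_forest: LCS vector (", paste(shown, collapse = ","), ")\n",
      sep = "")
  cat(length(x$components), "components:",
      paste(vapply(x$components, write_newick, character(1)),
            collapse = " "), "\n")
  invisible(x)
}

#' mHOP heuristic: minimum HOP distance over sampled taxon orders
#'
#' The mHOP distance of two trees is the minimum of the HOP distance over
#' all taxon orders; exact minimization is conjectured intractable, so this
#' heuristic samples `n_orders` random orders (always including the natural
#' sorted order) and reports the smallest distance found.  With fixed
#' `seed`, enlarging `n_orders` extends the same sample, so the result is
#' monotonically non-increasing in `n_orders`.
#'
#' @param t1,t2 [rooted_tree]s on the same leaf set.
#' @param n_orders number of sampled orders (>= 1).
#' @param seed integer RNG seed.
#' @return A list with `distance` (integer) and `order` (the best
#'   [taxon_order]).
#' @export
mhop_heuristic <- function(t1, t2, n_orders = 10, seed = 1) {
  l1 <- sort(t1$leaf_label[tree_leaves(t1)])
  l2 <- sort(t2$leaf_label[tree_leaves(t2)])
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  base <- default_order(t1)
  orders <- list(base)
  if (n_orders > 1L) {
    rng <- local_rng(seed)
    for (k in seq_len(n_orders - 1L))
      orders[[k + 1L]] <- taxon_order(sample(as.character(base)))
    restore_rng(rng)
  }
  best <- NULL; best_order <- NULL
  for (ord in orders) {
    d <- hop_distance(encode_tree(t1, ord), encode_tree(t2, ord))
    if (is.null(best) || d < best) {
      best <- d; best_order <- ord
    }
  }
  list(distance = best, order = best_order)
}

#' Robinson-Foulds distance for rooted trees
#'
#' The number of non-trivial clades (clusters) present in exactly one of
#' the two trees.  The normalized variant divides by a constant, by
#' default `2n` (the maximum over binary trees being `2(n - 2)`, the
#' conventional round constant `2n` matches large-scale benchmark usage).
#'
#' @param t1,t2 [rooted_tree]s on the same leaf set.
#' @param normalized divide by `norm_const`.
#' @param norm_const normalization constant; default `2 * n`.
#' @return Integer count, or numeric when `normalized = TRUE`.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE, norm_const = NULL) {
  l1 <- sort(t1$leaf_label[tree_leaves(t1)])
  l2 <- sort(t2$leaf_label[tree_leaves(t2)])
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  ord <- taxon_order(l1)
  c1 <- vapply(clade_set(t1, ord), paste, character(1), collapse = ",")
  c2 <- vapply(clade_set(t2, ord), paste, character(1), collapse = ",")
  d <- length(setdiff(c1, c2)) + length(setdiff(c2, c1))
  if (!normalized) return(as.integer(d))
  if (is.null(norm_const)) norm_const <- 2L * length(l1)
  d / norm_const
}
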