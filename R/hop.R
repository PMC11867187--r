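#' The HOP rearrangement
#'
#' A HOP move on taxon `i` (`i >= 2`) removes the first occurrence of `i`
#' from an LTSv vector and re-inserts it anywhere strictly after position 1
#' and not after the second occurrence of `i - 1`.  Every such move yields
#' a valid LTSv vector, and on trees it realizes a subtree
#' prune-and-regraft.  Insertion targets are expressed in post-removal
#' coordinates: `target` is the index the moved token occupies in the
#' resulting vector, with `2 <= target <= q` where `q` is the position of
#' `(i-1)_` after removal; re-creating the original vector is rejected as a
#' no-op.
#'
#' @param v an [ltsv] vector.
#' @param taxon taxon index `i`, `2 <= i <= n`.
#' @param target insertion index in the post-removal vector.
#' @return `apply_hop()`: the rearranged [ltsv] vector.
#' @examples
#' apply_hop(ltsv(c(1, 2, 3, 1, 2, 3)), taxon = 3, target = 4)
#' @export
apply_hop <- function(v, taxon, target) {
  if (!is_ltsv(v)) v <- ltsv(v)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  taxon <- as.integer(taxon); target <- as.integer(target)
  if (taxon < 2L || taxon > n)
    stop("illegal taxon: HOP moves apply to taxa 2..n, got ", taxon)
  fp <- first_positions(v)[taxon]
  w <- tokens[-fp]
  q <- second_positions_raw(w, n)[taxon - 1L]
  if (target < 2L || target > q)
    stop("target ", target, " outside the allowed range 2..", q,
         " for taxon ", taxon)
  if (target == fp)
    stop("no-op move: re-inserting taxon ", taxon,
         " at its original position")
  out <- append(w, taxon, after = target - 1L)
  ltsv(out)
}

# Second-occurrence positions for a raw token sequence in which one first
# occurrence may have been removed (so one taxon occurs once; its single
# occurrence is its second occurrence only if it had been seen... after
# removing a FIRST occurrence the remaining copy is the second one, and
# duplicated() marks it correctly relative to the other taxa).
second_positions_raw <- function(tokens, n) {
  seen <- logical(n)
  cnt <- tabulate(tokens, nbins = n)
  p <- integer(n)
  for (j in seq_along(tokens)) {
    t <- tokens[j]
    if (seen[t] || cnt[t] == 1L) p[t] <- j
    seen[t] <- TRUE
  }
  p
}

#' @rdname apply_hop
#' @return `enumerate_hop_moves()`: a data frame with columns `taxon` and
#'   `target`, one row per legal move (no-ops excluded).  The number of
#'   moves for taxon `i` is the post-removal position of `(i-1)_` minus 2.
#' @export
enumerate_hop_moves <- function(v) {
  if (!is_ltsv(v)) v <- ltsv(v)
  n <- length(unclass(v)) %/% 2L
  if (n < 2L) return(data.frame(taxon = integer(0), target = integer(0)))
  p <- second_positions(v)
  fp <- first_positions(v)
  taxa <- integer(0); targets <- integer(0)
  for (i in 2:n) {
    # removing the first occurrence of i (which lies before (i-1)_) shifts
    # (i-1)_ one slot left
    q <- p[i - 1L] - 1L
    if (q < 2L) next
    tg <- setdiff(2:q, fp[i])
    taxa <- c(taxa, rep(i, length(tg)))
    targets <- c(targets, tg)
  }
  data.frame(taxon = taxa, target = targets)
}

#' HOP neighbourhood
#'
#' All distinct LTSv vectors reachable from `v` by one HOP move.  Two moves
#' can yield the same vector only when they swap two adjacent first
#' occurrences (one moved right past the other, or vice versa), so the
#' distinct count equals the number of moves minus the number of such
#' adjacent pairs; `hop_neighbourhood_size()` uses that closed form and
#' runs in linear time, which makes neighbourhood-size experiments on
#' hundreds of taxa practical.
#'
#' @param v an [ltsv] vector.
#' @return `hop_neighbourhood()`: a list of distinct [ltsv] vectors.
#'   `hop_neighbourhood_size()`: an integer.
#' @export
hop_neighbourhood <- function(v) {
  if (!is_ltsv(v)) v <- ltsv(v)
  moves <- enumerate_hop_moves(v)
  out <- vector("list", nrow(moves))
  for (r in seq_len(nrow(moves)))
    out[[r]] <- apply_hop(v, moves$taxon[r], moves$target[r])
  keys <- vapply(out, function(w) paste(unclass(w), collapse = ","),
                 character(1))
  out[!duplicated(keys)]
}

#' @rdname hop_neighbourhood
#' @export
hop_neighbourhood_size <- function(v) {
  if (!is_ltsv(v)) v <- ltsv(v)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  if (n < 2L) return(0L)
  p <- second_positions(v)
  total <- sum(pmax(p[1:(n - 1L)] - 3L, 0L))
  sec <- second_occurrence_flags(tokens)
  # adjacent first-occurrence pairs starting at position >= 2 are counted
  # twice by the move enumeration (left token hops right vs right token
  # hops left)
  m <- length(tokens)
  dup <- sum(!sec[2:(m - 1L)] & !sec[3:m])
  as.integer(total - dup)
}

#' Shortest HOP path between two vectors
#'
#' Constructs a shortest sequence of HOP moves transforming `u` into `v`.
#' At each step the leftmost token of `v` that does not belong to the fixed
#' block-wise LCS witness between the current vector and `v` is moved into
#' the position it occupies in `v` (immediately after its predecessor
#' there); each move raises the HOP similarity by exactly one, so the path
#' length equals [hop_distance()].
#'
#' @param u,v [ltsv] vectors on the same number of taxa.
#' @return A data frame with columns `taxon` and `target` (the moves, in
#'   order); applying them to `u` with [apply_hop()] yields `v`.
#' @export
hop_path <- function(u, v) {
  if (!is_ltsv(u)) u <- ltsv(u)
  if (!is_ltsv(v)) v <- ltsv(v)
  if (length(u) != length(v))
    stop("vectors have different numbers of taxa")
  n <- length(unclass(u)) %/% 2L
  moves <- data.frame(taxon = integer(0), target = integer(0))
  cur <- u
  guard <- 0L
  while (!identical(as.integer(cur), as.integer(v))) {
    guard <- guard + 1L
    if (guard > n) stop("internal error: HOP path did not converge")
    bu <- canonical_decomposition(cur)
    bv <- canonical_decomposition(v)
    # block-wise LCS witnesses; positions of witness tokens in v
    pv <- second_positions(v)
    in_witness_v <- logical(2L * n)
    lo <- 1L
    for (i in seq_len(n - 1L)) {
      w <- lcs_partial_permutation(bu[[i]], bv[[i]], witness = TRUE)
      if (length(w$witness))
        in_witness_v[lo - 1L + w$positions_b] <- TRUE
      lo <- pv[i] + 1L
    }
    sec_v <- second_occurrence_flags(as.integer(v))
    cand <- which(!sec_v & !in_witness_v)
    j <- cand[1L]                        # leftmost dissimilar token of v
    x <- as.integer(v)[j]
    # predecessor token of x in v and its position in the current vector
    prev <- as.integer(v)[j - 1L]
    prev_is_sec <- sec_v[j - 1L]
    cur_tok <- as.integer(cur)
    fp <- first_positions(cur)
    pos_prev <- if (prev_is_sec) second_positions(cur)[prev] else fp[prev]
    # simulate removal of x's first occurrence, then insert after prev
    target <- if (fp[x] < pos_prev) pos_prev else pos_prev + 1L
    cur <- apply_hop(cur, x, target)
    moves <- rbind(moves, data.frame(taxon = x, target = target))
  }
  moves
}
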