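#' Neighbourhood-size experiment
#'
#' Generates random trees and computes, for each, the size of its HOP
#' neighbourhood (the number of distinct trees one HOP move away) under a
#' vector encoding.  By default the trees grow by pendant-edge attachment
#' and a single taxon order -- the insertion-order post-order traversal of
#' the first tree -- is used for every tree; `order_mode = "per_tree"`
#' instead encodes each tree under its own canonical post-order.
#'
#' @param n_trees number of random trees.
#' @param n_taxa taxa per tree.
#' @param seed integer seed.
#' @param attach attachment rule passed to [random_tree()].
#' @param order_mode `"first_tree"` (one shared order from tree 1) or
#'   `"per_tree"`.
#' @return A list with the per-tree integer vector `sizes` and the summary
#'   data frame `summary` (columns mean, sd, min, max).
#' @examples
#' bench_neighbourhood(10, 20, seed = 1)$summary
#' @export
bench_neighbourhood <- function(n_trees, n_taxa, seed = 1,
                                attach = "pendant",
                                order_mode = c("first_tree", "per_tree")) {
  stopifnot(n_trees >= 1, n_taxa >= 2)
  order_mode <- match.arg(order_mode)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  sizes <- integer(n_trees)
  ord <- NULL
  for (i in seq_len(n_trees)) {
    tr <- random_tree(n_taxa, attach = attach)
    if (order_mode == "first_tree") {
      if (i == 1L) ord <- taxa_orders(tr, "postorder_stored")
    } else {
      ord <- taxa_orders(tr, "postorder")
    }
    sizes[i] <- hop_neighbourhood_size(encode_tree(tr, ord))
  }
  list(sizes = sizes,
       summary = data.frame(mean = mean(sizes), sd = stats::sd(sizes),
                            min = min(sizes), max = max(sizes)))
}

#' SPR-walk correlation experiment
#'
#' Generates `n_focal` random trees; from each focal tree derives one tree
#' per entry of `spr_grid` by applying that many random SPR moves.  For
#' every (focal, derived) pair it computes the normalized
#' Robinson-Foulds distance and the normalized HOP distance under
#' `n_orders` random taxon orders (the same orders for every pair), plus
#' their per-pair mean.  Cumulative Pearson correlations between the SPR
#' count and each distance are reported over all pairs with SPR count at
#' most `k`, for `k` in `corr_grid`.
#'
#' @param n_focal number of focal trees.
#' @param n_taxa taxa per tree.
#' @param spr_grid numbers of SPR moves for the derived trees.
#' @param n_orders number of random taxon orders.
#' @param seed integer seed.
#' @param rf_norm,hop_norm normalization constants (defaults `2 * n_taxa`
#'   and `n_taxa`).
#' @param corr_grid thresholds `k` for the cumulative correlations.
#' @return A list with `pairs` (data frame: focal, spr, rf_norm, mean_hop,
#'   and one `hop_<j>` column per order) and `correlations` (data frame:
#'   k, rf, hop, mean_hop).
#' @export
bench_spr_correlation <- function(n_focal = 50, n_taxa = 100,
                                  spr_grid = seq(5, 100, by = 5),
                                  n_orders = 10, seed = 1,
                                  rf_norm = NULL, hop_norm = NULL,
                                  corr_grid = seq(10, 100, by = 10),
                                  attach = "pendant") {
  stopifnot(n_focal >= 1, all(diff(spr_grid) > 0))
  if (is.null(rf_norm)) rf_norm <- 2 * n_taxa
  if (is.null(hop_norm)) hop_norm <- n_taxa
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  labels <- paste0("t", seq_len(n_taxa))
  orders <- lapply(seq_len(n_orders), function(j) taxon_order(sample(labels)))
  rows <- vector("list", n_focal * length(spr_grid))
  ri <- 0L
  for (f in seq_len(n_focal)) {
    focal <- random_tree(n_taxa, attach = attach)
    enc_focal <- lapply(orders, function(o) encode_tree(focal, o))
    for (k in spr_grid) {
      derived <- random_spr(focal, k)
      hops <- vapply(seq_len(n_orders), function(j)
        hop_distance(enc_focal[[j]], encode_tree(derived, orders[[j]])) /
          hop_norm, numeric(1))
      rf <- rf_distance(focal, derived) / rf_norm
      ri <- ri + 1L
      row <- c(focal = f, spr = k, rf_norm = rf, mean_hop = mean(hops),
               stats::setNames(hops, paste0("hop_", seq_len(n_orders))))
      rows[[ri]] <- row
    }
  }
  pairs <- as.data.frame(do.call(rbind, rows))
  correlations <- do.call(rbind, lapply(corr_grid, function(k) {
    sub <- pairs[pairs$spr <= k, ]
    hop_cols <- grep("^hop_", names(sub))
    pooled_spr <- rep(sub$spr, times = length(hop_cols))
    pooled_hop <- unlist(sub[hop_cols], use.names = FALSE)
    data.frame(k = k,
               rf = stats::cor(sub$spr, sub$rf_norm),
               hop = stats::cor(pooled_spr, pooled_hop),
               mean_hop = stats::cor(sub$spr, sub$mean_hop))
  }))
  list(pairs = pairs, correlations = correlations)
}
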