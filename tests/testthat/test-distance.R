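test_that("partial-permutation LCS matches examples and the DP oracle", {
  expect_equal(lcs_partial_permutation(c(1, 3, 2), c(1, 2, 3))$length, 2L)
  expect_equal(lcs_partial_permutation(integer(0), 4)$length, 0L)
  expect_error(lcs_partial_permutation(c(1, 1), 2), "partial permutation")
  w <- lcs_partial_permutation(c(1, 3, 2), c(1, 2, 3), witness = TRUE)
  expect_equal(w$witness, c(1L, 3L))  # earliest-position witness
  set.seed(2)
  for (rep in 1:1000) {
    m <- sample(0:12, 1); k <- sample(0:12, 1)
    pool <- sample(1:20)
    a <- pool[seq_len(m)]
    b <- sample(1:20, k)
    got <- lcs_partial_permutation(a, b, witness = TRUE)
    expect_equal(got$length, dp_lcs_length(a, b))
    expect_length(got$witness, got$length)
    if (got$length) {
      # the witness is a genuine common subsequence
      expect_identical(a[got$positions_a], got$witness)
      expect_identical(b[got$positions_b], got$witness)
      expect_true(all(diff(got$positions_a) > 0))
      expect_true(all(diff(got$positions_b) > 0))
    }
  }
})

test_that("HOP similarity reproduces the worked sum", {
  u <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
  v <- ltsv(c(1, 2, 3, 1, 4, 2, 3, 4))
  expect_equal(hop_similarity(u, v), 2L)
  expect_equal(hop_distance(u, v), 2L)
  expect_equal(hop_similarity(ltsv(c(1, 2, 3, 4, 1, 2, 3, 4)),
                              ltsv(c(1, 2, 1, 3, 2, 4, 3, 4))), 2L)
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    w <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    expect_equal(hop_similarity(w, w), n)
    expect_equal(hop_distance(w, w), 0L)
  }
  expect_error(hop_similarity(u, ltsv(c(1, 2, 1, 2))), "different")
})

test_that("hop_distance equals BFS distance exhaustively at n = 4", {
  vecs <- enumerate_ltsv(4)
  for (a in vecs) {
    dist <- bfs_hop_distances(a)
    for (b in vecs)
      expect_equal(hop_distance(a, b), dist[[vec_key(b)]])
  }
})

test_that("hop_distance equals BFS distance on random 5-taxon pairs", {
  vecs <- enumerate_ltsv(5)
  set.seed(55)
  dist_cache <- list()
  for (rep in 1:2000) {
    ij <- sample.int(length(vecs), 2, replace = TRUE)
    a <- vecs[[ij[1]]]; b <- vecs[[ij[2]]]
    ka <- vec_key(a)
    if (is.null(dist_cache[[ka]])) dist_cache[[ka]] <- bfs_hop_distances(a)
    expect_equal(hop_distance(a, b), dist_cache[[ka]][[vec_key(b)]])
  }
})

test_that("the HOP distance is a metric", {
  # symmetry and identity on random pairs
  set.seed(6)
  for (rep in 1:200) {
    n <- sample(2:25, 1)
    ord <- taxon_order(paste0("t", 1:n))
    a <- encode_tree(random_tree(n), ord)
    b <- encode_tree(random_tree(n), ord)
    expect_equal(hop_distance(a, b), hop_distance(b, a))
    expect_equal(hop_distance(a, b) == 0L,
                 identical(as.integer(a), as.integer(b)))
    expect_lte(hop_distance(a, b), n - 1)
  }
  # triangle inequality on all 15^3 triples at n = 4
  vecs <- enumerate_ltsv(4)
  d <- matrix(0L, 15, 15)
  for (i in 1:15) for (j in 1:15)
    d[i, j] <- hop_distance(vecs[[i]], vecs[[j]])
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    expect_lte(d[i, k], d[i, j] + d[j, k])
})

test_that("caterpillar and ladder vectors realize distance n - 2", {
  for (n in 4:10) {
    caterpillar <- ltsv(c(seq_len(n), seq_len(n)))
    ladder <- ltsv(as.integer(c(1, 2, 1,
                                unlist(lapply(3:n, function(k) c(k, k - 1))),
                                n)))
    expect_equal(hop_distance(caterpillar, ladder), n - 2)
  }
})

test_that("common_forest reproduces the worked example", {
  u <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
  v <- ltsv(c(1, 2, 3, 1, 4, 2, 3, 4))
  cf <- common_forest(u, v)
  shown <- ifelse(cf$lcs_second, paste0(cf$lcs_tokens, "_"), cf$lcs_tokens)
  expect_equal(paste(shown, collapse = ","), "1,3,1_,2_,3_,4_")
  expect_length(cf$components, 3)
  expect_equal(cf$component_taxa, list(c(1L, 3L), 2L, 4L))
  nwk <- vapply(cf$components, write_newick, character(1))
  expect_setequal(nwk, c("(1,3);", "(2);", "(4);"))
  # identical trees give a single component
  cf2 <- common_forest(u, u)
  expect_length(cf2$components, 1)
  expect_true(trees_equal(cf2$components[[1]], decode_tree(u)))
  # caterpillar vs ladder at n = 4
  cf3 <- common_forest(ltsv(c(1, 2, 3, 4, 1, 2, 3, 4)),
                       ltsv(c(1, 2, 1, 3, 2, 4, 3, 4)))
  expect_equal(cf3$component_taxa, list(c(1L, 2L), 3L, 4L))
})

test_that("common-forest components are restrictions of both trees", {
  set.seed(60)
  for (n in 4:5) {
    vecs <- enumerate_ltsv(n)
    for (rep in 1:40) {
      ij <- sample.int(length(vecs), 2)
      u <- vecs[[ij[1]]]; v <- vecs[[ij[2]]]
      cf <- common_forest(u, v)
      tu <- decode_tree(u); tv <- decode_tree(v)
      for (ci in seq_along(cf$components)) {
        taxa <- as.character(cf$component_taxa[[ci]])
        if (length(taxa) < 2) next
        expect_true(trees_equal(cf$components[[ci]],
                                restrict_to_taxa(tu, taxa)))
        expect_true(trees_equal(cf$components[[ci]],
                                restrict_to_taxa(tv, taxa)))
      }
      # components partition the taxon set
      expect_identical(sort(unlist(cf$component_taxa)), seq_len(n))
    }
  }
})

test_that("mhop heuristic finds the exhaustive minimum on 5 taxa", {
  set.seed(40)
  t1 <- random_tree(5, labels = as.character(1:5))
  t2 <- random_spr(t1, 2)
  perms <- combinat_perms(as.character(1:5))
  exhaustive <- min(vapply(perms, function(p) {
    o <- taxon_order(p)
    hop_distance(encode_tree(t1, o), encode_tree(t2, o))
  }, integer(1)))
  got <- mhop_heuristic(t1, t2, n_orders = 400, seed = 9)
  expect_equal(got$distance, exhaustive)
  expect_equal(mhop_heuristic(t1, t1, n_orders = 3, seed = 1)$distance, 0L)
  # never worse than the sorted-order distance; non-increasing in n_orders
  base <- hop_distance(encode_tree(t1, taxon_order(as.character(1:5))),
                       encode_tree(t2, taxon_order(as.character(1:5))))
  expect_lte(got$distance, base)
  d5 <- mhop_heuristic(t1, t2, n_orders = 5, seed = 2)$distance
  d20 <- mhop_heuristic(t1, t2, n_orders = 20, seed = 2)$distance
  expect_lte(d20, d5)
})

test_that("rf_distance counts symmetric clade differences", {
  t1 <- parse_newick("((1,2),(3,4));")
  t2 <- parse_newick("((1,3),(2,4));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 4L)
  expect_equal(rf_distance(t1, t2, normalized = TRUE), 4 / 8)
  expect_equal(rf_distance(t1, t2, normalized = TRUE, norm_const = 4), 1)
  # caterpillars differing by the bottom cherry
  a <- parse_newick("(1,(2,(3,(4,5))));")
  b <- parse_newick("(1,(2,(4,(3,5))));")
  expect_equal(rf_distance(a, b), 2L)
  expect_error(rf_distance(t1, parse_newick("(1,2);")), "leaf sets")
})
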