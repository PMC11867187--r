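test_that("apply_hop performs the illustrated move and validates", {
  # moving 3 from before 2 to just before 2_ turns (1,3,2,1_,2_,4,3_,4_)
  # into (1,2,1_,3,2_,4,3_,4_)
  v <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
  out <- apply_hop(v, taxon = 3, target = 4)
  expect_identical(as.integer(out), c(1L, 2L, 1L, 3L, 2L, 4L, 3L, 4L))
  expect_identical(as.integer(apply_hop(ltsv(c(1, 2, 3, 1, 2, 3)), 3, 4)),
                   c(1L, 2L, 1L, 3L, 2L, 3L))
  expect_error(apply_hop(v, 1, 2), "illegal taxon")
  expect_error(apply_hop(v, 3, 7), "range")
  expect_error(apply_hop(v, 2, 3), "no-op")
})

test_that("move enumeration counts and misses nothing", {
  expect_equal(nrow(enumerate_hop_moves(ltsv(c(1, 2, 1, 2)))), 0)
  m3 <- enumerate_hop_moves(ltsv(c(1, 2, 3, 1, 2, 3)))
  expect_equal(nrow(m3), 3)
  expect_equal(sum(m3$taxon == 2), 1)
  expect_equal(sum(m3$taxon == 3), 2)
  # against brute force over all (taxon, slot) insertions
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(3:20, 1)
    v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    tok <- as.integer(v)
    fp <- ltsvtree:::first_positions(v)
    brute <- character(0)
    for (i in 2:n) {
      w <- tok[-fp[i]]
      for (d in seq_len(2 * n)) {
        cand <- append(w, i, after = d - 1L)
        if (identical(cand, tok)) next
        if (validate_ltsv(cand)$valid)
          brute <- c(brute, paste(cand, collapse = ","))
      }
    }
    moves <- enumerate_hop_moves(v)
    got <- vapply(seq_len(nrow(moves)), function(r)
      vec_key(apply_hop(v, moves$taxon[r], moves$target[r])), character(1))
    expect_setequal(unique(got), unique(brute))
  }
})

test_that("the neighbourhood is exact, symmetric, and at distance one", {
  nb <- hop_neighbourhood(ltsv(c(1, 2, 3, 1, 2, 3)))
  expect_length(nb, 2)  # the two other trees on 3 taxa
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    nb <- hop_neighbourhood(v)
    expect_equal(hop_neighbourhood_size(v), length(nb))
    expect_lte(length(nb), 2 * (n - 1)^2)
    for (w in nb) {
      expect_true(validate_ltsv(as.integer(w))$valid)
      expect_equal(hop_distance(v, w), 1L)
    }
    # symmetry on a sampled neighbour
    w <- nb[[sample.int(length(nb), 1)]]
    expect_true(vec_key(v) %in% vapply(hop_neighbourhood(w), vec_key,
                                       character(1)))
  }
})

test_that("every move is reversible", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    moves <- enumerate_hop_moves(v)
    for (r in sample.int(nrow(moves), min(10, nrow(moves)))) {
      w <- apply_hop(v, moves$taxon[r], moves$target[r])
      back <- enumerate_hop_moves(w)
      keys <- vapply(seq_len(nrow(back)), function(b)
        vec_key(apply_hop(w, back$taxon[b], back$target[b])), character(1))
      expect_true(vec_key(v) %in% keys)
    }
  }
})

test_that("the HOP graph is connected for n = 4 and n = 5", {
  for (n in 4:5) {
    vecs <- enumerate_ltsv(n)
    expect_length(vecs, prod(seq(1, 2 * n - 3, by = 2)))
    dist <- bfs_hop_distances(vecs[[1]])
    expect_length(dist, length(vecs))
    # the left-to-right normalization reaches the caterpillar vector
    cat_vec <- ltsv(c(seq_len(n), seq_len(n)))
    expect_true(!is.null(dist[[vec_key(cat_vec)]]))
  }
})

test_that("HOP neighbours are SPR neighbours of the decoded tree", {
  for (n in 4:5) {
    set.seed(n)
    vecs <- sample(enumerate_ltsv(n), 6)
    for (v in vecs) {
      tr <- decode_tree(v)
      spr_keys <- spr_neighbourhood_keys(tr)
      for (w in hop_neighbourhood(v))
        expect_true(tree_key(decode_tree(w)) %in% spr_keys)
    }
  }
})

test_that("neighbourhood size grows quadratically in n", {
  set.seed(77)
  mean_size <- function(n) {
    mean(vapply(1:40, function(i) {
      v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
      as.numeric(hop_neighbourhood_size(v))
    }, numeric(1)))
  }
  m25 <- mean_size(25); m50 <- mean_size(50); m100 <- mean_size(100)
  expect_gt(m50 / m25, 3);  expect_lt(m50 / m25, 5)
  expect_gt(m100 / m50, 3); expect_lt(m100 / m50, 5)
})

test_that("left-to-right normalization reaches the caterpillar vector", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    moves <- 0L
    for (i in 2:n) {
      fp <- ltsvtree:::first_positions(v)
      if (fp[i] == fp[i - 1] + 1) next       # already right after i - 1
      tgt <- if (fp[i] < fp[i - 1]) fp[i - 1] else fp[i - 1] + 1L
      v <- apply_hop(v, i, tgt)
      moves <- moves + 1L
    }
    expect_identical(as.integer(v), c(seq_len(n), seq_len(n)))
    expect_lte(moves, n - 1)
  }
})

test_that("encoding and distance remain practical on thousands of taxa", {
  set.seed(101)
  n <- 5000
  t1 <- random_tree(n, branch_lengths = FALSE)
  t2 <- random_tree(n, branch_lengths = FALSE)
  ord <- taxa_orders(t1, "alphabetical")
  v1 <- encode_tree(t1, ord); v2 <- encode_tree(t2, ord)
  expect_length(as.integer(v1), 2 * n)
  d <- hop_distance(v1, v2)
  expect_gt(d, 0); expect_lte(d, n - 1)
  expect_true(trees_equal(decode_tree(v1, ord), t1))
})

test_that("hop_path is a shortest valid path", {
  u <- ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
  v <- ltsv(c(1, 2, 3, 1, 4, 2, 3, 4))
  expect_equal(nrow(hop_path(u, u)), 0)
  p <- hop_path(u, v)
  expect_equal(nrow(p), 2)
  # exhaustively: path length equals BFS distance for all 4-taxon pairs
  vecs <- enumerate_ltsv(4)
  for (a in vecs) {
    dist <- bfs_hop_distances(a)
    for (b in vecs) {
      p <- hop_path(a, b)
      cur <- a
      for (r in seq_len(nrow(p))) {
        cur <- apply_hop(cur, p$taxon[r], p$target[r])
        expect_true(validate_ltsv(as.integer(cur))$valid)
      }
      expect_identical(as.integer(cur), as.integer(b))
      expect_equal(nrow(p), dist[[vec_key(b)]])
      expect_equal(nrow(p), hop_distance(a, b))
    }
  }
})
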