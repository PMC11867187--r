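# A small hand-built network: taxa 1..3, one reticulation feeding leaf 3.
hand_network <- function() {
  edges <- rbind(c(7, 6), c(6, 4), c(6, 5), c(4, 1), c(4, 8),
                 c(5, 2), c(5, 8), c(8, 3))
  tree_child_network(edges, c("1", "2", "3", rep(NA_character_, 5)))
}

test_that("network validation enforces structure and the tree-child rule", {
  net <- hand_network()
  expect_equal(length(reticulations(net)), 1)
  # both children of nodes 6 and 7 are reticulations -> violation
  bad <- rbind(c(9, 8), c(8, 6), c(8, 7), c(6, 4), c(6, 5), c(7, 4),
               c(7, 5), c(4, 1), c(5, 2))
  expect_error(tree_child_network(bad, c("1", "2",
                                         rep(NA_character_, 7))),
               "tree-child")
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 1))
  expect_error(tree_child_network(cyc, rep(NA_character_, 3)))
})

test_that("tree components: count, top component, index permutation", {
  ord3 <- taxon_order(as.character(1:3))
  comps <- tree_components(hand_network(), ord3)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$root, 7)          # top component holds the root
  expect_equal(comps[[1]]$taxa, c(1L, 2L))
  expect_equal(comps[[2]]$taxa, 3L)
  # a plain tree has a single component
  tr <- network_from_tree(parse_newick("((1,2),(3,4));"))
  ct <- tree_components(tr, taxon_order(as.character(1:4)))
  expect_length(ct, 1)
  set.seed(31)
  net3 <- random_tree_child_network(10, 3)
  expect_length(tree_components(net3), 4)
})

test_that("encoding matches the hand-worked vector and the tree case", {
  ord3 <- taxon_order(as.character(1:3))
  v <- encode_network(hand_network(), ord3)
  expect_identical(as.integer(v), c(1L, 2L, 3L, 1L, 3L, 2L, 3L))
  expect_equal(sum(tabulate(as.integer(v)) == 3), 1)
  # r = 0: identical to the plain tree encoding
  tr <- parse_newick("((1,2),(3,4));")
  ord4 <- taxon_order(as.character(1:4))
  v0 <- encode_network(network_from_tree(tr), ord4)
  expect_identical(as.integer(v0), as.integer(encode_tree(tr, ord4)))
})

test_that("decoding a tree vector through the network codec gives the tree", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(2:15, 1)
    ord <- taxon_order(as.character(1:n))
    tr <- random_tree(n, labels = as.character(1:n))
    v <- encode_tree(tr, ord)
    net <- decode_network(as.integer(v), ord)
    expect_length(reticulations(net), 0)
    expect_true(trees_equal(ltsvtree:::network_to_tree(net),
                            decode_tree(v, ord)))
  }
})

test_that("round trip is the identity on generated networks", {
  set.seed(99)
  configs <- expand.grid(n = c(5, 10, 20, 30), r = c(0, 2, 5, 8))
  configs <- configs[configs$r <= configs$n - 1, ]
  reps <- 0
  for (ci in seq_len(nrow(configs))) {
    for (k in 1:4) {
      n <- configs$n[ci]; r <- configs$r[ci]
      net <- random_tree_child_network(n, r)
      expect_length(reticulations(net), r)
      ord <- default_network_order(net)
      v <- encode_network(net, ord)
      expect_equal(sum(tabulate(as.integer(v),
                                nbins = length(ord)) == 3L), r)
      expect_equal(length(as.integer(v)), 2 * n + r)
      back <- decode_network(v, ord)
      expect_true(networks_isomorphic(net, back, ord))
      reps <- reps + 1
    }
  }
  expect_gte(reps, 50)
})

test_that("single-token corruption is almost always detected", {
  set.seed(13)
  detected <- 0; total <- 0
  for (rep in 1:25) {
    net <- random_tree_child_network(8, 2)
    ord <- default_network_order(net)
    v <- as.integer(encode_network(net, ord))
    for (k in 1:8) {
      w <- v
      pos <- sample.int(length(w), 1)
      w[pos] <- sample(setdiff(seq_len(length(ord)), w[pos]), 1)
      total <- total + 1
      bad <- tryCatch({
        back <- decode_network(w, ord)
        # decodable corruptions must at least differ from the original
        !networks_isomorphic(net, back, ord)
      }, error = function(e) TRUE)
      if (bad) detected <- detected + 1
    }
  }
  expect_gte(detected / total, 0.99)
})

test_that("extended Newick round-trips networks", {
  net <- hand_network()
  txt <- write_enewick(net)
  expect_match(txt, "#H1", fixed = TRUE)
  expect_true(networks_isomorphic(net, parse_enewick(txt),
                                  taxon_order(as.character(1:3))))
  set.seed(41)
  for (rep in 1:10) {
    nt <- random_tree_child_network(12, 3)
    ord <- default_network_order(nt)
    expect_true(networks_isomorphic(nt, parse_enewick(write_enewick(nt)),
                                    ord))
  }
})
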