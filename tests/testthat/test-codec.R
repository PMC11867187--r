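test_that("internal labelling follows the min rule", {
  # the worked 5-taxon tree: edges (6,8),(8,7),(7,1),(7,2),(8,10),(10,9),
  # (9,3),(9,4),(10,5)
  parent <- rep(NA_integer_, 10)
  parent[c(8, 7, 1, 2, 10, 9, 3, 4, 5)] <- c(6, 8, 7, 7, 8, 10, 9, 9, 10)
  tr <- rooted_tree(parent, c(as.character(1:5), rep(NA, 5)))
  lab <- label_internal_nodes(tr, taxon_order(as.character(1:5)))
  expect_equal(lab$label[6:10], c(1L, 2L, 3L, 4L, 5L))

  cherry <- parse_newick("(1,2);")
  labc <- label_internal_nodes(cherry, taxon_order(c("1", "2")))
  expect_equal(sort(labc$label[!is.na(labc$label)]), c(1L, 2L))
  expect_equal(labc$label[cherry$root], 1L)

  cat4 <- parse_newick("(1,(2,(3,4)));")
  lab4 <- label_internal_nodes(cat4, taxon_order(as.character(1:4)))
  expect_identical(sort(lab4$label[!is.na(lab4$label)]), 1:4)
  expect_error(label_internal_nodes(parse_newick("(1,2,3);"),
                                    taxon_order(as.character(1:3))),
               "outdegree")
})

test_that("encode_tree reproduces the printed vectors", {
  parent <- rep(NA_integer_, 10)
  parent[c(8, 7, 1, 2, 10, 9, 3, 4, 5)] <- c(6, 8, 7, 7, 8, 10, 9, 9, 10)
  tr5 <- rooted_tree(parent, c(as.character(1:5), rep(NA, 5)))
  expect_identical(as.integer(encode_tree(tr5, taxon_order(as.character(1:5)))),
                   c(1L, 3L, 2L, 1L, 2L, 5L, 4L, 3L, 4L, 5L))
  expect_identical(as.integer(encode_tree(parse_newick("(1,2);"))),
                   c(1L, 2L, 1L, 2L))
  expect_identical(as.integer(encode_tree(parse_newick("((1,2),(3,4));"))),
                   c(1L, 3L, 2L, 1L, 2L, 4L, 3L, 4L))
})

test_that("decode_tree emits the printed edge table in scan order", {
  v <- ltsv(c(1, 3, 2, 1, 2, 5, 4, 3, 4, 5))
  ed <- decode_edges(v)
  expect_equal(unname(ed[, 1]), c(6, 8, 7, 7, 8, 10, 9, 9, 10))
  expect_equal(unname(ed[, 2]), c(8, 7, 1, 2, 10, 9, 3, 4, 5))
  tr <- decode_tree(v)
  expect_equal(tr$root, 6)
  expect_identical(as.integer(encode_tree(tr, taxon_order(as.character(1:5)))),
                   as.integer(v))
  expect_equal(unname(decode_edges(ltsv(c(1, 1)))), matrix(c(2L, 1L), 1, 2))
})

test_that("encode and decode are mutually inverse bijections (n = 3, 4, 5)", {
  for (n in 3:5) {
    trees <- enumerate_trees(n)
    expect_length(trees, prod(seq(1, 2 * n - 3, by = 2)))
    ord <- taxon_order(as.character(seq_len(n)))
    encs <- vapply(trees, function(tr)
      paste(as.integer(encode_tree(tr, ord)), collapse = ","), character(1))
    expect_equal(anyDuplicated(encs), 0L)
    for (tr in trees)
      expect_true(trees_equal(decode_tree(encode_tree(tr, ord)), tr))
    # the reverse direction: every valid vector decodes then re-encodes
    # to itself
    for (v in enumerate_ltsv(n))
      expect_identical(as.integer(encode_tree(decode_tree(v), ord)),
                       as.integer(v))
  }
})

test_that("first occurrences map to internal nodes, second to leaves", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    v <- encode_tree(random_tree(n), taxon_order(paste0("t", 1:n)))
    sec <- duplicated(as.integer(v))
    expect_equal(sum(sec), n)
    ed <- decode_edges(v)
    expect_setequal(ed[ed[, 2] <= n, 2], seq_len(n))   # one edge per leaf
    expect_setequal(ed[, 1], n + seq_len(n))           # one node per taxon
    expect_true(all(ed[, 1] > n))
  }
})

test_that("multifurcating encoding handles the printed polytomy example", {
  # ((1,2,4),3) rooted: one polytomy below the root child
  tr <- parse_newick("((1,2,4),3);")
  mv <- encode_multifurcating(tr, taxon_order(as.character(1:4)))
  expect_equal(format(mv), "(1,3,{2 4},1_,2_,3_,4_)")
  expect_equal(multi_ltsv_length(mv), 2 * 4 + 2 * 1)
  back <- decode_multifurcating(mv)
  expect_true(trees_equal(back, tr))

  star <- parse_newick("(1,2,3,4);")
  ms <- encode_multifurcating(star, taxon_order(as.character(1:4)))
  groups <- Filter(function(e) e$type == "group", ms$elements)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$taxa, c(2L, 3L, 4L))
  expect_equal(multi_ltsv_length(ms), 2 * 4 + 2)
})

test_that("multifurcating encoding of binary trees matches encode_tree", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    tr <- random_tree(n)
    ord <- taxa_orders(tr, "alphabetical")
    mv <- encode_multifurcating(tr, ord)
    expect_true(all(vapply(mv$elements, function(e) e$type != "group",
                           logical(1))))
    flat <- unlist(lapply(mv$elements, function(e) e$taxa))
    expect_identical(as.integer(flat), as.integer(encode_tree(tr, ord)))
    expect_equal(multi_ltsv_length(mv), 2L * n)
  }
})

test_that("multifurcating round trip holds under random edge contractions", {
  set.seed(57)
  for (rep in 1:100) {
    n <- sample(3:15, 1)
    tr <- random_tree(n, branch_lengths = FALSE,
                      labels = as.character(1:n))
    # contract a random subset of internal (non-root-child) edges
    nodes <- ltsvtree:::tree_nodes(tr)
    internal <- nodes[is.na(tr$leaf_label[nodes]) & !is.na(tr$parent[nodes]) &
                        tr$parent[nodes] != tr$root]
    contract <- internal[stats::runif(length(internal)) < 0.4]
    parent <- tr$parent
    for (v in contract) {
      kids <- which(!is.na(parent) & parent == v)
      parent[kids] <- parent[v]
      parent[v] <- NA_integer_
    }
    # drop contracted slots
    parent[contract] <- NA_integer_
    mt <- rooted_tree(parent, tr$leaf_label)
    ord <- taxon_order(as.character(1:n))
    mv <- encode_multifurcating(mt, ord)
    t_poly <- sum(vapply(mv$elements, function(e) e$type == "group",
                         logical(1)))
    expect_equal(multi_ltsv_length(mv), 2 * n + 2 * t_poly)
    expect_true(trees_equal(decode_multifurcating(mv, ord), mt))
  }
})
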