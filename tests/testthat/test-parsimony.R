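test_that("character lengths match the worked examples", {
  t4 <- parse_newick("((A,B),(C,D));")
  m <- matrix_from_states(rbind(A = 0, B = 0, C = 1, D = 1))
  expect_equal(character_length(t4, m, 1), 1L)
  m2 <- matrix_from_states(rbind(A = 0, B = 1, C = 0, D = 1))
  expect_equal(character_length(t4, m2, 1), 2L)
  # ordered vs unordered with states 0/2
  st <- rbind(A = 0, B = 0, C = 2, D = 2)
  mo <- matrix_from_states(st, ordered = TRUE, nstates = 3)
  mu <- matrix_from_states(st, ordered = FALSE, nstates = 3)
  expect_equal(character_length(t4, mo, 1), 2L)
  expect_equal(character_length(t4, mu, 1), 1L)
  expect_error(character_length(t4, m, 5), "out of range")
})

test_that("tree_length reproduces the F1 fixture report", {
  m <- fixture_f1()
  lr <- tree_length(parse_newick("((A,B),(C,D));"), m)
  expect_equal(lr$L, 5)
  expect_equal(unname(lr$per_character), c(1L, 2L, 2L))
  expect_equal(lr$M, 3)
  expect_equal(lr$G, 6)
  expect_equal(lr$CI, 0.6)
  expect_equal(lr$RI, 1 / 3)
  # three-way tie
  expect_equal(tree_length(parse_newick("((A,C),(B,D));"), m)$L, 5)
  expect_equal(tree_length(parse_newick("((A,D),(B,C));"), m)$L, 5)
})

test_that("constant matrix yields zero length and undefined indices", {
  m <- matrix_from_states(rbind(A = c(0, 0), B = c(0, 0), C = c(0, 0),
                                D = c(0, 0)), nstates = 2)
  expect_warning(lr <- tree_length(parse_newick("((A,B),(C,D));"), m),
                 "undefined")
  expect_equal(lr$L, 0)
  expect_true(is.nan(lr$CI))
})

test_that("lengths equal brute-force labeling minima (oracle equivalence)", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    m <- random_matrix(n, n_chars = 4, max_states = 3, p_missing = 0.15,
                       p_ordered = 0.4)
    phy <- random_tree(n)
    for (j in seq_len(4)) {
      expect_equal(character_length(phy, m, j), brute_char_length(phy, m, j),
                   info = sprintf("i=%d j=%d", i, j))
    }
  }
})

test_that("length is rooting-invariant and additive over characters", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    m <- random_matrix(n, n_chars = 6, max_states = 3, p_missing = 0.1)
    phy <- random_tree(n)
    lr <- tree_length(phy, m)
    expect_equal(lr$L, sum(lr$per_character))
    rr <- parsikit:::.normalize_tree(
      ape::root(phy, outgroup = sample(phy$tip.label, 1), resolve.root = TRUE))
    expect_equal(tree_length(rr, m)$L, lr$L)
  }
})

test_that("ancestral state sets match the worked examples", {
  t4 <- parse_newick("((A,B),(C,D));")
  m <- matrix_from_states(rbind(A = 0, B = 0, C = 1, D = 1))
  mpr <- ancestral_states(t4, m, 1)
  internals <- mpr$node_states[5:6]
  expect_equal(lengths(internals), c(1L, 1L))
  expect_equal(sort(unlist(internals)), c(0L, 1L))
  expect_equal(nrow(mpr$changes), 1)
  expect_equal(mpr$changes$status, "unambiguous")
  expect_false(mpr$changes$terminal)

  m2 <- matrix_from_states(rbind(A = 0, B = 1, C = 0, D = 1))
  mpr2 <- ancestral_states(t4, m2, 1)
  expect_equal(mpr2$node_states[[5]], 0:1)
  expect_equal(mpr2$node_states[[6]], 0:1)
  expect_true(all(mpr2$changes$status == "ambiguous"))

  mc <- matrix_from_states(rbind(A = 0, B = 0, C = 0, D = 0), nstates = 2)
  mpr3 <- ancestral_states(t4, mc, 1)
  expect_equal(nrow(mpr3$changes), 0)
  expect_true(all(vapply(mpr3$node_states, identical, logical(1), 0L)))
})

test_that("MPR node sets equal brute-force optimal-assignment unions", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    m <- random_matrix(n, n_chars = 2, max_states = 3, p_missing = 0.1,
                       p_ordered = 0.5)
    phy <- random_tree(n)
    for (j in 1:2) {
      mpr <- ancestral_states(phy, m, j)
      oracle <- brute_mpr_sets(phy, m, j)
      expect_equal(mpr$length, oracle$length)
      n_tip <- length(phy$tip.label)
      for (v in (n_tip + 1):(n_tip + phy$Nnode)) {
        expect_equal(sort(mpr$node_states[[v]]), oracle$sets[[v]],
                     info = sprintf("i=%d j=%d node=%d", i, j, v))
      }
    }
  }
})

test_that("rule-1 collapsing contracts exactly the unforced edges", {
  # an edge carrying an unambiguous change is kept
  m <- matrix_from_states(rbind(A = 0, B = 0, C = 1, D = 1))
  t4 <- parse_newick("((A,B),(C,D));")
  expect_equal(tree_hash(collapse_zero_length(t4, m)), tree_hash(t4))
  # 5-leaf tree with an internal edge used by no character under any MPR
  m5 <- matrix_from_states(rbind(A = c(0, 0), B = c(0, 0), C = c(0, 1),
                                 D = c(0, 1), E = c(0, 1)))
  t5 <- parse_newick("((A,B),((C,D),E));")
  c5 <- collapse_zero_length(t5, m5)
  expect_equal(attr(bipartitions(c5), "keys"), "C,D,E")
  expect_equal(tree_length(c5, m5)$L, tree_length(t5, m5)$L)
  # star input is unchanged
  star <- parse_newick("(A,B,C,D);")
  expect_equal(tree_hash(collapse_zero_length(star, m)), tree_hash(star))
})
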