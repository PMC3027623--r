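test_that("Wagner addition is seeded, deterministic, and near-optimal on clean data", {
  fx <- fixture_clean8()
  w1 <- random_addition_wagner(fx$matrix, seed = 3)
  w2 <- random_addition_wagner(fx$matrix, seed = 3)
  expect_equal(tree_hash(w1), tree_hash(w2))
  # noiseless congruent characters: any addition sequence reaches the
  # generating tree's length
  true_len <- tree_length(fx$tree, fx$matrix)$L
  for (s in 1:5) {
    w <- random_addition_wagner(fx$matrix, seed = s)
    expect_equal(tree_length(w, fx$matrix)$L, true_len)
  }
  # 4 taxa: result is one of the 3 topologies and never the worst
  m <- fixture_f1()
  w4 <- random_addition_wagner(m, seed = 1)
  expect_equal(length(w4$tip.label), 4)
  expect_lte(tree_length(w4, m)$L, 5)
})

test_that("TBR search finds the global optimum from a poor start", {
  m <- fixture_f1()
  res <- tbr_search(parse_newick("((A,B),(C,D));"), m,
                    search_config(hold = 10))
  expect_equal(res$best_length, 5)  # all 3 topologies tie at 5
  fx <- fixture_clean8()
  true_len <- tree_length(fx$tree, fx$matrix)$L
  set.seed(8)
  for (i in 1:5) {
    start <- random_tree(8, labels = sort(fx$tree$tip.label))
    res <- tbr_search(start, fx$matrix, search_config())
    expect_equal(res$best_length, true_len)
  }
})

test_that("suboptimal mode retains exactly the trees within the slack", {
  # worked Bremer fixture: two characters support AB|CD, one AC|BD;
  # topology lengths are 4 / 5 / 6
  m <- matrix_from_states(rbind(A = c(0, 0, 0), B = c(0, 0, 1),
                                C = c(1, 1, 0), D = c(1, 1, 1)))
  res <- tbr_search(parse_newick("((A,B),(C,D));"), m,
                    search_config(hold = 20, slack = 1, collapse = "none"))
  lens <- vapply(res$trees, function(t) tree_length(t, m)$L, numeric(1))
  expect_equal(res$best_length, 4)
  expect_setequal(lens, c(4, 5))
  expect_length(res$trees, 2)
})

test_that("replicated_search recovers the enumerated optimum and full MPT set", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    m <- random_matrix(n, n_chars = 6, max_states = 3, p_missing = 0.1)
    ets <- enum_topologies(LETTERS[seq_len(n)])
    lens <- vapply(ets, etree_len, numeric(1), cm = m)
    best <- min(lens)
    opt_hash <- unique(vapply(ets[lens == best], function(et)
      tree_hash(collapse_zero_length(etree_phylo(et), m)), ""))
    res <- replicated_search(m, search_config(n_replicates = 5, seed = i))
    expect_equal(res$best_length, best)
    expect_setequal(vapply(res$trees, tree_hash, ""), opt_hash)
  }
})

test_that("search results are reproducible from the master seed", {
  m <- fixture_clean8()$matrix
  cfg <- search_config(n_replicates = 2, seed = 77)
  r1 <- replicated_search(m, cfg)
  r2 <- replicated_search(m, cfg)
  expect_equal(r1$best_length, r2$best_length)
  expect_equal(r1$log, r2$log)
  expect_equal(r1$replicate_hits, r2$replicate_hits)
  expect_equal(vapply(r1$trees, tree_hash, ""), vapply(r2$trees, tree_hash, ""))
})

test_that("constrained searches respect and price the constraint", {
  m <- fixture_f1()
  res <- constrained_search(m, constraint(c("A", "C")),
                            search_config(n_replicates = 3, seed = 4))
  expect_equal(res$best_length, 5)
  expect_true(all(vapply(res$trees, satisfies_constraint, logical(1),
                         constr = constraint(c("A", "C")))))
  # forbidding a strongly supported clade costs steps
  fx <- fixture_clean8()
  un <- replicated_search(fx$matrix, search_config(n_replicates = 3, seed = 5))
  con <- constrained_search(fx$matrix, constraint(c("A", "B"), "forbid"),
                            search_config(n_replicates = 3, seed = 6))
  expect_gt(con$best_length, un$best_length)
  # a constraint already satisfied is free
  con2 <- constrained_search(fx$matrix, constraint(c("A", "B")),
                             search_config(n_replicates = 3, seed = 7))
  expect_equal(con2$best_length, un$best_length)
})

test_that("constrained optimum is monotone in the constraint set", {
  set.seed(41)
  fx <- fixture_clean8()
  g1 <- constraint(list(c("A", "E")))
  g2 <- constraint(list(c("A", "E"), c("B", "G")))
  cfg <- search_config(n_replicates = 3, seed = 9)
  b1 <- constrained_search(fx$matrix, g1, cfg)$best_length
  b2 <- constrained_search(fx$matrix, g2, cfg)$best_length
  un <- replicated_search(fx$matrix, cfg)$best_length
  expect_gte(b1, un)
  expect_gte(b2, b1)
})
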