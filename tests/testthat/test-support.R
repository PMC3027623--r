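test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- parse_newick("((A,B),((C,D),E));")
  expect_equal(tree_hash(strict_consensus(list(t1, t1))), tree_hash(t1))
  ties <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                 parse_newick)
  expect_length(bipartitions(strict_consensus(ties)), 0)
  t2 <- parse_newick("((A,B),((C,E),D));")
  cons <- strict_consensus(list(t1, t2))
  expect_equal(attr(bipartitions(cons), "keys"), "C,D,E")
  expect_error(strict_consensus(list(t1, parse_newick("((A,B),(C,D));"))),
               "mismatched leaf sets")
})

test_that("consensus bipartitions equal the intersection on random inputs", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    labs <- paste0("t", seq_len(n))
    trees <- lapply(1:4, function(j) random_tree(n, labels = labs))
    cons <- strict_consensus(trees)
    expected <- Reduce(intersect, lapply(trees, function(t)
      attr(bipartitions(t), "keys")))
    expect_setequal(attr(bipartitions(cons), "keys"), expected)
  }
})

test_that("reduced consensus commutes with pruning", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(7:11, 1)
    labs <- paste0("t", seq_len(n))
    trees <- lapply(1:3, function(j) random_tree(n, labels = labs))
    drop <- sample(labs, 2)
    a <- reduced_consensus(trees, drop)
    b <- strict_consensus(lapply(trees, prune_taxa, drop = drop))
    expect_equal(tree_hash(a), tree_hash(b))
  }
  t1 <- parse_newick("((A,B),((C,D),E));")
  t2 <- parse_newick("((A,B),((C,E),D));")
  expect_equal(tree_hash(reduced_consensus(list(t1, t2))),
               tree_hash(strict_consensus(list(t1, t2))))
})

test_that("pruning a taxon floating between two positions restores resolution", {
  # E invades a different cherry in each tree, destroying shared splits
  t1 <- parse_newick("((A,(B,E)),((C,D),(F,G)));")
  t2 <- parse_newick("((A,B),((C,(D,E)),(F,G)));")
  rc <- reduced_consensus(list(t1, t2), "E")
  expect_gt(length(bipartitions(rc)), length(bipartitions(strict_consensus(list(t1, t2)))))
  expect_equal(length(bipartitions(rc)), 3)  # fully resolved on 6 leaves
})

test_that("unstable-taxon identification finds the rogue and its cause", {
  t1 <- parse_newick("((A,(B,E)),((C,D),(F,G)));")
  t2 <- parse_newick("((A,B),((C,(D,E)),(F,G)));")
  rep <- identify_unstable_taxa(list(t1, t2))
  expect_equal(rep$taxon, "E")
  expect_equal(rep$n_positions, 2)
  expect_true(all(rep$gain > 0))
  # identical trees: nothing to prune
  expect_equal(nrow(identify_unstable_taxa(list(t1, t1))), 0)
  # a taxon scored '?' everywhere is missing-data unstable
  fx <- fixture_clean8()
  labs <- sort(fx$tree$tip.label)
  states <- sapply(rep(fx$clades, each = 3), function(cl)
    as.integer(labs %in% cl))
  states <- rbind(states, NA_integer_)
  rownames(states) <- c(labs, "R")
  m2 <- matrix_from_states(states)
  # keep the MPTs binary: with an all-missing taxon, rule-1 collapsing
  # would itself dissolve the resolution the instability test looks for
  res <- replicated_search(m2, search_config(n_replicates = 3, seed = 2,
                                             hold = 30, collapse = "none",
                                             final_buffer_limit = 200))
  rep2 <- identify_unstable_taxa(res$trees, m2)
  expect_true("R" %in% rep2$taxon)
  expect_equal(rep2$cause[rep2$taxon == "R"], "missing_data")
})

test_that("Bremer supports match enumeration on small fixtures", {
  # worked fixture: lengths 4/5/6 across the 3 topologies -> bremer 1;
  # duplicating the supporting characters -> 3
  m <- matrix_from_states(rbind(A = c(0, 0, 0), B = c(0, 0, 1),
                                C = c(1, 1, 0), D = c(1, 1, 1)))
  res <- replicated_search(m, search_config(n_replicates = 3, seed = 1))
  br <- bremer_supports(m, res, search_config(n_replicates = 3, seed = 2))
  expect_equal(br$bremer[br$group == "C,D"], 1)
  m2 <- matrix_from_states(rbind(A = c(0, 0, 0, 0, 0), B = c(0, 0, 1, 0, 0),
                                 C = c(1, 1, 0, 1, 1), D = c(1, 1, 1, 1, 1)))
  res2 <- replicated_search(m2, search_config(n_replicates = 3, seed = 1))
  br2 <- bremer_supports(m2, res2, search_config(n_replicates = 3, seed = 2))
  expect_equal(br2$bremer[br2$group == "C,D"], 3)
})

test_that("reverse-constraint Bremer equals enumeration on random matrices", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(5:7, 1)
    m <- random_matrix(n, n_chars = 8, max_states = 2)
    ets <- enum_topologies(LETTERS[seq_len(n)])
    lens <- vapply(ets, etree_len, numeric(1), cm = m)
    best <- min(lens)
    opt <- lapply(ets[lens == best], etree_phylo)
    res <- replicated_search(m, search_config(n_replicates = 5, seed = i,
                                              hold = 30))
    expect_equal(res$best_length, best)
    br <- bremer_supports(m, res, search_config(n_replicates = 4, seed = i))
    keys_per_tree <- lapply(ets, function(et)
      parsikit:::.etree_splits(et))
    for (r in seq_len(nrow(br))) {
      lacking <- vapply(keys_per_tree, function(ks) !(br$group[r] %in% ks),
                        logical(1))
      expect_equal(br$bremer[r], min(lens[lacking]) - best,
                   info = sprintf("i=%d group=%s", i, br$group[r]))
    }
  }
})

test_that("sweep Bremer bounds agree with exact values when deep enough", {
  m <- matrix_from_states(rbind(A = c(0, 0, 0), B = c(0, 0, 1),
                                C = c(1, 1, 0), D = c(1, 1, 1)))
  res <- replicated_search(m, search_config(n_replicates = 3, seed = 1))
  sw <- bremer_supports(m, res, search_config(n_replicates = 3, seed = 3),
                        method = "suboptimal_sweep", slack = 3)
  expect_equal(sw$bremer[sw$group == "C,D"], 1)
})

test_that("resampling frequencies respect their definitions and bounds", {
  fx <- fixture_clean8()
  cfg <- search_config(n_replicates = 2, hold = 5, seed = 13)
  res <- replicated_search(fx$matrix, search_config(n_replicates = 3, seed = 1))
  bs <- resampling_support(fx$matrix, cfg, "bootstrap", n_reps = 40,
                           mpts = res)
  expect_true(all(bs$absolute >= 0 & bs$absolute <= 100))
  expect_true(all(bs$gc >= -100 & bs$gc <= 100))
  expect_true(all(bs$gc <= bs$absolute))
  jk <- resampling_support(fx$matrix, cfg, "jackknife", n_reps = 40,
                           mpts = res)
  expect_true(all(jk$gc <= jk$absolute))
  # noiseless congruent signal: every true clade nearly always recovered
  expect_true(all(bs$absolute >= 90))
})

test_that("GC frequency hits its defining bounds in degenerate cases", {
  # single dominant character: group recovered in every pseudoreplicate
  # that has any data; never contradicted
  labs <- LETTERS[1:6]
  states <- cbind(as.integer(labs %in% c("E", "F")),
                  as.integer(labs %in% c("E", "F")),
                  as.integer(labs %in% c("E", "F")))
  rownames(states) <- labs
  m <- matrix_from_states(states)
  bs <- resampling_support(m, search_config(n_replicates = 2, seed = 3),
                           "bootstrap", n_reps = 20, groups = "E,F")
  expect_equal(bs$absolute, 100)
  expect_equal(bs$gc, 100)
})
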