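# sacral-style state alphabet used throughout
sac_states <- c("S1+S2", "DS+S1+S2", "S1+S2+CS", "DS+S1+S2+CS")

test_that("discrete mapping finds a single unambiguous gain on a pectinate tree", {
  tr <- parse_newick("(A,(B,(C,(D,(E,F)))));")
  vals <- c(A = "S1+S2", B = "DS+S1+S2", C = "DS+S1+S2", D = "DS+S1+S2",
            E = "DS+S1+S2+CS", F = "DS+S1+S2+CS")
  rec <- map_discrete_trait(tr, discrete_trait("sacrum", vals, sac_states))
  gains <- rec$changes[rec$changes$to == "DS+S1+S2+CS", , drop = FALSE]
  expect_equal(nrow(gains), 1)
  expect_equal(gains$flag, "synapomorphy_unambiguous")
  expect_equal(gains$from, "DS+S1+S2")
})

test_that("a mid-tree deviant is flagged as a terminal autapomorphy", {
  tr <- parse_newick("(A,(B,(C,(D,(E,F)))));")
  vals <- c(A = "S1+S2", B = "DS+S1+S2", C = "S1+S2+CS", D = "DS+S1+S2",
            E = "DS+S1+S2+CS", F = "DS+S1+S2+CS")
  rec <- map_discrete_trait(tr, discrete_trait("sacrum", vals, sac_states))
  dev <- rec$changes[rec$changes$to == "S1+S2+CS", , drop = FALSE]
  expect_equal(nrow(dev), 1)
  expect_equal(dev$flag, "autapomorphy")
  expect_true(dev$child <= length(tr$tip.label))
})

test_that("constant and degenerate traits behave", {
  tr <- parse_newick("((A,B),(C,D));")
  rec <- map_discrete_trait(tr, discrete_trait("x", c(A = "s", B = "s",
                                                      C = "s", D = "s")))
  expect_equal(rec$cost, 0)
  expect_equal(nrow(rec$changes), 0)
  expect_error(map_discrete_trait(tr, discrete_trait("x",
    c(A = NA, B = NA, C = NA, D = NA), states = "s")), "missing")
})

test_that("discrete mapping cost equals the character-length machinery", {
  set.seed(71)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    tr <- random_tree(n)
    k <- sample(2:4, 1)
    st <- sample(0:(k - 1), n, replace = TRUE)
    vals <- setNames(letters[st + 1], tr$tip.label)
    rec <- map_discrete_trait(tr, discrete_trait("x", vals,
                                                 states = letters[1:k]))
    m <- matrix_from_states(matrix(st, n, 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            nstates = k)
    expect_equal(rec$cost, character_length(tr, m, 1))
  }
})

test_that("clade diagnosis recovers the constructed synapomorphies", {
  fx <- fixture_clean8()
  res <- replicated_search(fx$matrix, search_config(n_replicates = 3, seed = 3))
  # clade {E,F,G,H} was built with 3 supporting characters (13-15); the
  # same bipartition is also supported by characters 16-18 ({A,B,C,D})
  d <- diagnose_clade(res$trees, fx$matrix, c("E", "F", "G", "H"))
  expect_setequal(d$character, 13:18)
  expect_true(all(d$status == "unambiguous"))
  expect_error(diagnose_clade(res$trees, fx$matrix, c("A", "E")),
               "not monophyletic")
})

test_that("ambiguous stem changes are reported as ambiguous", {
  # two MPR classes (L = 2): changes on the C and D terminals, or on the
  # E terminal plus the {C,D,E} stem -- so the stem change is ambiguous
  m <- matrix_from_states(rbind(A = 0, B = 0, C = 1, D = 1, E = 0))
  tr <- parse_newick("((A,B),(C,(D,E)));")
  d <- diagnose_clade(list(tr), m, c("C", "D", "E"))
  expect_equal(nrow(d), 1)
  expect_equal(d$status, "ambiguous")
})

test_that("linear parsimony reconstructs the worked continuous fixtures", {
  t4 <- parse_newick("((A,B),(C,D));")
  rec <- reconstruct_continuous(t4, continuous_trait("x", c(A = 1, B = 1,
                                                            C = 3, D = 3)))
  expect_equal(rec$cost, 2)
  internals <- rec$node_interval[5:6, , drop = FALSE]
  expect_setequal(internals[, 1], c(1, 3))
  expect_equal(internals[, 1], internals[, 2])
  # all equal leaves: zero cost, all nodes at the common value
  rec2 <- reconstruct_continuous(t4, continuous_trait("x", c(A = 2, B = 2,
                                                             C = 2, D = 2)))
  expect_equal(rec2$cost, 0)
  expect_true(all(rec2$node_interval == 2))
  # extreme cherry: the hub stays at the majority value
  t3 <- parse_newick("(A,B,C);")
  rec3 <- reconstruct_continuous(t3, continuous_trait("x", c(A = 0.5, B = 10,
                                                             C = 0.5)))
  expect_equal(rec3$cost, 9.5)
  hub <- rec3$node_interval[4, ]
  expect_equal(unname(hub), c(0.5, 0.5))
})

test_that("linear parsimony cost matches a discretized grid oracle", {
  grid_oracle <- function(phy, vals) {
    obs <- vals[phy$tip.label]
    grid <- sort(unique(obs))
    n_tip <- length(phy$tip.label)
    combos <- expand.grid(rep(list(grid), phy$Nnode))
    best <- Inf
    for (g in seq_len(nrow(combos))) {
      st <- c(obs, as.numeric(combos[g, ]))
      tot <- sum(abs(st[phy$edge[, 1]] - st[phy$edge[, 2]]))
      best <- min(best, tot)
    }
    best
  }
  set.seed(72)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    vals <- setNames(round(runif(n, 1, 10), 1), tr$tip.label)
    rec <- reconstruct_continuous(tr, continuous_trait("x", vals))
    expect_equal(rec$cost, grid_oracle(tr, vals), tolerance = 1e-9)
  }
})

test_that("node intervals are tight", {
  # shrinking an interval endpoint strictly increases achievable cost:
  # check via the grid oracle with the node pinned just inside
  t4 <- parse_newick("((A,B),(C,D));")
  vals <- c(A = 1, B = 2, C = 5, D = 7)
  rec <- reconstruct_continuous(t4, continuous_trait("x", vals))
  pin_cost <- function(node, value) {
    # cost when `node` is pinned to `value`, others free (grid search)
    grid <- sort(unique(c(vals, value)))
    other <- setdiff(5:6, node)
    best <- Inf
    for (g in grid) {
      st <- c(vals, NA, NA)
      st[node] <- value; st[other] <- g
      best <- min(best, sum(abs(st[t4$edge[, 1]] - st[t4$edge[, 2]])))
    }
    best
  }
  for (v in 5:6) {
    lo <- rec$node_interval[v, 1]; hi <- rec$node_interval[v, 2]
    expect_equal(pin_cost(v, lo), rec$cost)
    expect_equal(pin_cost(v, hi), rec$cost)
    if (lo > min(vals)) expect_gt(pin_cost(v, lo - 0.25), rec$cost)
    if (hi < max(vals)) expect_gt(pin_cost(v, hi + 0.25), rec$cost)
  }
})

test_that("squared-change variant solves the neighbor-mean system", {
  t4 <- parse_newick("((A,B),(C,D));")
  rec <- reconstruct_continuous(t4, continuous_trait("x", c(A = 1, B = 1,
                                                            C = 3, D = 3)),
                                method = "squared")
  # symmetric case: internal nodes between their cherries and each other
  iv <- rec$node_interval
  expect_equal(unname(iv[5, 1] + iv[6, 1]), 4, tolerance = 1e-9)
  expect_lt(rec$cost, 4.001)
})
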