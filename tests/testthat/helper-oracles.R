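# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's scoring path: lengths come from exhaustive enumeration of
# internal-node labelings, optima from exhaustive topology enumeration.

# -- fixtures --------------------------------------------------------------

# the 4-taxon worked fixture: per-character lengths 1,2,2 on ((A,B),(C,D))
fixture_f1 <- function() {
  matrix_from_states(rbind(A = c(0, 0, 0), B = c(0, 1, 1),
                           C = c(1, 0, 1), D = c(1, 1, 0)))
}

# 8 taxa, 18 noiseless binary characters: 3 congruent characters per clade
# of a fixed balanced tree
fixture_clean8 <- function(chars_per_clade = 3) {
  tr <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  labs <- sort(tr$tip.label)
  clades <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"),
                 c("A", "B", "C", "D"), c("E", "F", "G", "H"))
  states <- sapply(rep(clades, each = chars_per_clade),
                   function(cl) as.integer(labs %in% cl))
  rownames(states) <- labs
  list(tree = tr, matrix = matrix_from_states(states), clades = clades)
}

# -- topology enumeration --------------------------------------------------

# all unrooted binary topologies on the given labels, as internal etrees
enum_topologies <- function(labs) {
  grow <- function(et) {
    i <- length(et$tips) + 1L
    lapply(seq_len(nrow(et$edges)), function(r)
      parsikit:::.attach_tip(et, r, i, labs[i], max(et$edges) + 1L))
  }
  ets <- list(parsikit:::.star3(labs[1:3], 1:3, hub = length(labs) + 1L))
  while (length(ets[[1]]$tips) < length(labs))
    ets <- unlist(lapply(ets, grow), recursive = FALSE)
  ets
}

etree_phylo <- function(et) parsikit:::.etree_to_phylo(et)
tree_hash <- function(phy) parsikit:::.etree_hash(parsikit:::.phylo_to_etree(phy))

# fast exact length of an etree (C++ Sankoff, shared with the package but
# used here only to score enumerated topologies; the labeling oracle below
# is fully independent)
etree_len <- function(et, cm, pk = NULL) {
  taxa <- names(et$tips)
  if (is.null(pk)) pk <- parsikit:::.pack_matrix(cm, taxa = taxa)
  sum(parsikit:::score_edges_cpp(et$edges, unname(et$tips), pk$mask,
                                 pk$nstates, pk$ordered) * pk$weights)
}

# score a list of enumerated etrees sharing one tip layout
enum_lengths <- function(ets, cm) {
  pk <- parsikit:::.pack_matrix(cm, taxa = names(ets[[1]]$tips))
  vapply(ets, etree_len, numeric(1), cm = cm, pk = pk)
}

# -- brute-force labeling oracle ------------------------------------------

# minimal steps of character j by enumerating every assignment of states
# to internal nodes of the (arbitrarily rooted) tree
brute_char_length <- function(phy, cm, j) {
  rows <- match(phy$tip.label, cm$taxa)
  masks <- cm$cells[rows, j]
  k <- cm$nstates[j]
  ordered <- cm$ordered[j]
  n_tip <- length(phy$tip.label)
  internal <- (n_tip + 1):(n_tip + phy$Nnode)
  edge <- phy$edge
  cost <- function(a, b) if (ordered) abs(a - b) else as.integer(a != b)
  leaf_opts <- lapply(seq_len(n_tip), function(v) parsikit:::.mask_states(masks[v]))
  grid <- expand.grid(rep(list(0:(k - 1)), length(internal)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_int <- as.integer(grid[g, ])
    state_of <- function(v) {
      if (v <= n_tip) leaf_opts[[v]] else assign_int[v - n_tip]
    }
    tot <- 0
    for (r in seq_len(nrow(edge))) {
      a <- state_of(edge[r, 1]); b <- state_of(edge[r, 2])
      # leaves may be ambiguous: take their cheapest choice (valid because
      # each leaf appears in exactly one edge)
      tot <- tot + min(outer(a, b, cost))
    }
    best <- min(best, tot)
  }
  best
}

# union of optimal internal-state assignments, by the same enumeration
brute_mpr_sets <- function(phy, cm, j) {
  rows <- match(phy$tip.label, cm$taxa)
  masks <- cm$cells[rows, j]
  k <- cm$nstates[j]
  ordered <- cm$ordered[j]
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  edge <- phy$edge
  cost <- function(a, b) if (ordered) abs(a - b) else as.integer(a != b)
  leaf_opts <- lapply(seq_len(n_tip), function(v) parsikit:::.mask_states(masks[v]))
  # enumerate internal AND ambiguous-leaf choices jointly for exactness
  choice_sets <- c(leaf_opts, rep(list(0:(k - 1)), n_int))
  grid <- expand.grid(choice_sets)
  lens <- apply(grid, 1, function(st) {
    sum(vapply(seq_len(nrow(edge)), function(r)
      cost(st[edge[r, 1]], st[edge[r, 2]]), numeric(1)))
  })
  best <- min(lens)
  opt <- grid[lens == best, , drop = FALSE]
  sets <- lapply(seq_len(ncol(grid)), function(v) sort(unique(opt[, v])))
  list(length = best, sets = sets)
}

# random matrix generator used across property tests
random_matrix <- function(n_taxa, n_chars, max_states = 2, p_missing = 0,
                          p_ordered = 0) {
  labs <- LETTERS[seq_len(n_taxa)]
  ks <- sample(2:max_states, n_chars, replace = TRUE)
  states <- sapply(ks, function(k) sample(0:(k - 1), n_taxa, replace = TRUE))
  states <- matrix(as.integer(states), n_taxa, dimnames = list(labs, NULL))
  if (p_missing > 0)
    states[matrix(runif(length(states)) < p_missing, nrow(states))] <- NA
  matrix_from_states(states, ordered = runif(n_chars) < p_ordered)
}

random_tree <- function(n, labels = LETTERS[seq_len(n)])
  simulate_tree(n, seed = sample.int(1e6, 1), labels = labels)
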