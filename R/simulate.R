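#' @title Synthetic matrices, trees and traits
#' @description Generators with the statistical structure morphological
#'   parsimony analysis assumes: discrete characters evolved by a Poisson
#'   number of state changes placed on the edges of a known tree
#'   (symmetric moves for unordered characters, +/-1 steps for ordered
#'   ones), then degraded cell-wise with missing and polymorphic entries.
#'   Change counts rather than continuous-time rates are simulated because
#'   parsimony never consumes branch lengths and this gives direct control
#'   of homoplasy.
#' @name synthetic_data
NULL

#' Simulation settings
#'
#' @param n_chars number of characters.
#' @param n_states alphabet size per character (recycled; or a function
#'   of no arguments returning one draw).
#' @param frac_ordered fraction of characters treated as ordered.
#' @param rate expected number of state changes per character on the
#'   whole tree (Poisson mean).
#' @param missing_frac per-cell probability of degradation to missing.
#' @param poly_frac per-cell probability of degradation to a polymorphic
#'   state set (adds one extra state).
#' @param fragmentary named numeric vector: per-taxon missing
#'   probabilities that override `missing_frac` for chosen rows (the
#'   "fragmentary taxon" mode used to reproduce rogue-taxon behavior).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chars = 100, n_states = 2, frac_ordered = 0,
                           rate = 1, missing_frac = 0, poly_frac = 0,
                           fragmentary = NULL) {
  stopifnot(n_chars >= 1, missing_frac >= 0, missing_frac <= 1,
            poly_frac >= 0, poly_frac <= 1, frac_ordered >= 0,
            frac_ordered <= 1, rate >= 0)
  structure(list(n_chars = as.integer(n_chars), n_states = n_states,
                 frac_ordered = frac_ordered, rate = rate,
                 missing_frac = missing_frac, poly_frac = poly_frac,
                 fragmentary = fragmentary),
            class = "synthetic_spec")
}

#' Uniform random unrooted binary topology
#'
#' Sequential leaf addition onto a uniformly chosen edge, which yields the
#' uniform distribution over the `(2n-5)!!` labelled unrooted binary
#' topologies.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed.
#' @param labels leaf labels; default `t01, t02, ...`.
#' @return A `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  stopifnot(n_taxa >= 4)
  if (is.null(labels))
    labels <- sprintf("t%0*d", max(2, nchar(n_taxa)), seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  if (!is.null(seed)) set.seed(seed)
  et <- .star3(labels[1:3], 1:3, hub = n_taxa + 1L)
  for (i in seq_len(n_taxa)[-(1:3)]) {
    r <- sample.int(nrow(et$edges), 1)
    et <- .attach_tip(et, r, i, labels[i], max(et$edges) + 1L)
  }
  .etree_to_phylo(et)
}

#' Evolve a character matrix on a known tree
#'
#' Each character receives a Poisson number of changes assigned to
#' uniformly chosen edges and propagated from a random root state;
#' unordered characters jump to a uniformly chosen different state,
#' ordered characters move one step (reflecting at the ends).  Cells are
#' then degraded to missing or polymorphic at the spec fractions.
#' Constant characters are retained.
#'
#' @param tree a `phylo` (the generating topology).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return A [char_matrix()].
#' @export
simulate_matrix <- function(tree, spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  labels <- tree$tip.label
  n <- length(labels)
  edge <- tree$edge
  n_node <- n + tree$Nnode
  root <- setdiff(edge[, 1], edge[, 2])[1]
  ord <- integer(0); stack <- root
  children <- split(seq_len(nrow(edge)), edge[, 1])
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    kid <- children[[as.character(v)]]
    if (!is.null(kid)) stack <- c(stack, edge[kid, 2])
  }
  nc <- spec$n_chars
  draw_k <- if (is.function(spec$n_states)) {
    function() spec$n_states()
  } else {
    ks <- rep_len(spec$n_states, nc)
    i <- 0
    function() { i <<- i + 1; ks[i] }
  }
  states <- matrix(NA_integer_, n, nc, dimnames = list(labels, NULL))
  ordered <- runif(nc) < spec$frac_ordered
  kvec <- integer(nc)
  for (j in seq_len(nc)) {
    k <- as.integer(draw_k())
    kvec[j] <- max(k, 2L)
    k <- kvec[j]
    n_changes <- rpois(1, spec$rate)
    ch_edges <- if (n_changes > 0)
      sample.int(nrow(edge), n_changes, replace = TRUE) else integer(0)
    node_state <- integer(n_node)
    node_state[root] <- sample.int(k, 1) - 1L
    for (v in ord[-1]) {
      r <- which(edge[, 2] == v)
      s <- node_state[edge[r, 1]]
      for (hit in seq_len(sum(ch_edges == r))) {
        s <- if (ordered[j]) {
          if (s == 0L) 1L else if (s == k - 1L) k - 2L
          else s + sample(c(-1L, 1L), 1)
        } else {
          sample(setdiff(0:(k - 1L), s), 1)
        }
      }
      node_state[v] <- s
    }
    states[, j] <- node_state[seq_len(n)]
  }
  cm <- matrix_from_states(states, taxa = labels, ordered = ordered,
                           nstates = kvec)
  # degradation
  pmiss <- rep(spec$missing_frac, n)
  if (!is.null(spec$fragmentary)) {
    idx <- match(names(spec$fragmentary), labels)
    pmiss[idx[!is.na(idx)]] <- spec$fragmentary[!is.na(idx)]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(nc)) {
      u <- runif(1)
      if (u < pmiss[i]) {
        cm$cells[i, j] <- .full_mask(cm$nstates[j])
        cm$tag[i, j] <- "missing"
      } else if (u < pmiss[i] + spec$poly_frac && cm$nstates[j] >= 2) {
        cur <- .mask_states(cm$cells[i, j])
        extra <- sample(setdiff(0:(cm$nstates[j] - 1L), cur), 1)
        cm$cells[i, j] <- .bitmask(c(cur, extra))
        cm$tag[i, j] <- "uncertain"
      }
    }
  }
  cm
}

#' A study-scale synthetic fixture
#'
#' A deterministic (seeded) 50-taxon, 277-character data set shaped like a
#' basal-sauropodomorph matrix: a known generating tree whose backbone
#' walks from outgroups to a derived large-bodied clade, roughly 40%
#' missing cells with two heavily incomplete (fragmentary) taxa, a
#' sacral-configuration trait with nested gains
#' (S1+S2 -> DS+S1+S2 -> DS+S1+S2+CS -> 2DS+S1+S2+CS) plus one
#' autapomorphic deviation (S1+S2+CS on a mid-tree terminal), and a
#' femoral-width (FML) trait increasing toward the derived clade with one
#' small-bodied exception nested inside it.  All data are synthetic; the
#' fixture only mimics the qualitative structure of such studies.
#'
#' @param seed integer seed.
#' @return A list: `matrix`, `tree`, `sacral` ([discrete_trait()]),
#'   `fml` ([continuous_trait()]), and `roles` naming the special taxa.
#' @export
basal_sauropodomorph_fixture <- function(seed = 1) {
  set.seed(seed)
  n <- 50
  labels <- sprintf("taxon_%02d", seq_len(n))
  # pectinate backbone: taxon_01 (outgroup) to taxon_40, then a derived
  # crown of 10
  et <- .star3(labels[1:3], 1:3, hub = n + 1L)
  for (i in 4:n) {
    # attach each new taxon to the terminal edge of the previous one,
    # giving a ladder; every 7th taxon attaches one step back (side twig)
    target_tip <- if (i %% 7 == 0) i - 2L else i - 1L
    r <- which(et$edges[, 2] == target_tip | et$edges[, 1] == target_tip)[1]
    et <- .attach_tip(et, r, i, labels[i], max(et$edges) + 1L)
  }
  tree <- .etree_to_phylo(et)
  rogue <- c("taxon_23", "taxon_31")
  frag <- setNames(rep(0.95, length(rogue)), rogue)
  spec <- synthetic_spec(n_chars = 277, n_states = c(rep(2, 200), rep(3, 60),
                                                     rep(4, 17)),
                         frac_ordered = 0.1, rate = 1.6,
                         missing_frac = 0.38, poly_frac = 0.01,
                         fragmentary = frag)
  cm <- simulate_matrix(tree, spec, seed = seed + 1L)
  # sacral configuration: nested gains along the ladder, one deviant
  sac_states <- c("S1+S2", "DS+S1+S2", "S1+S2+CS", "DS+S1+S2+CS",
                  "2DS+S1+S2+CS")
  depth <- as.integer(sub("taxon_", "", labels))
  sac <- ifelse(depth <= 12, "S1+S2",
                ifelse(depth <= 38, "DS+S1+S2",
                       ifelse(depth <= 48, "DS+S1+S2+CS", "2DS+S1+S2+CS")))
  names(sac) <- labels
  deviant <- "taxon_20"
  sac[deviant] <- "S1+S2+CS"     # autapomorphic caudosacral gain
  sac[sample(labels[4:16], 3)] <- NA  # some taxa lack sacra
  sacral <- discrete_trait("sacral_configuration", sac, states = sac_states)
  # FML: grows along the backbone; one small-bodied exception in the
  # derived (four-sacral) clade
  small <- "taxon_41"
  fml <- 2 + 28 * (pmax(depth - 10, 0) / (n - 10))^2
  fml <- fml * exp(rnorm(n, 0, 0.08))
  names(fml) <- labels
  fml[small] <- 4
  fml[sample(labels, 8)] <- NA   # femora not preserved everywhere
  fml[small] <- 4                # keep the exception observed
  fml_trait <- continuous_trait("FML", fml)
  list(matrix = cm, tree = tree, sacral = sacral, fml = fml_trait,
       roles = list(outgroup = labels[1], rogue = rogue,
                    sacral_deviant = deviant, small_bodied = small,
                    derived_clade = labels[depth > 38]))
}
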