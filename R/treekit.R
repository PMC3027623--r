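#' @title Tree utilities for parsimony analysis
#' @description Trees are held as unrooted `ape::phylo` objects; any display
#'   rooting (e.g. on an outgroup) is presentational only, since parsimony
#'   length is rooting-invariant.  Internally, search code manipulates plain
#'   edge lists over arbitrary node ids ("etrees") and converts at the
#'   surface.
#' @name treekit
NULL

# ---- internal etree representation --------------------------------------
# list(edges = 2-col integer matrix over arbitrary ids,
#      tips  = named integer vector: taxon label -> node id)

.phylo_to_etree <- function(phy) {
  list(edges = phy$edge,
       tips = setNames(seq_len(length(phy$tip.label)), phy$tip.label))
}

.etree_newick <- function(et) {
  adj <- .etree_adj(et)
  tipset <- et$tips
  label_of <- setNames(names(tipset), as.character(tipset))
  ids <- unique(as.vector(et$edges))
  internal <- setdiff(ids, tipset)
  root <- if (length(internal)) internal[1] else et$edges[1, 1]
  build <- function(v, from) {
    nb <- setdiff(adj[[as.character(v)]], from)
    if (!length(nb)) return(label_of[[as.character(v)]])
    kids <- vapply(nb, build, "", from = v)
    inner <- paste(kids, collapse = ",")
    if (!is.na(match(v, tipset))) {
      # a tip with further neighbors cannot occur in well-formed trees
      paste0("(", inner, ")", label_of[[as.character(v)]])
    } else paste0("(", inner, ")")
  }
  paste0(build(root, -1L), ";")
}

.etree_to_phylo <- function(et) {
  phy <- ape::read.tree(text = .etree_newick(et))
  .normalize_tree(phy)
}

.etree_adj <- function(et) {
  adj <- list()
  for (i in seq_len(nrow(et$edges))) {
    a <- as.character(et$edges[i, 1]); b <- as.character(et$edges[i, 2])
    adj[[a]] <- c(adj[[a]], et$edges[i, 2])
    adj[[b]] <- c(adj[[b]], et$edges[i, 1])
  }
  adj
}

# leaf labels on the child side of every edge; list parallel to edge rows
.etree_edge_leafsets <- function(et) {
  n_e <- nrow(et$edges)
  adj <- list()
  for (i in seq_len(n_e)) {
    a <- as.character(et$edges[i, 1]); b <- as.character(et$edges[i, 2])
    adj[[a]] <- rbind(adj[[a]], c(et$edges[i, 2], i))
    adj[[b]] <- rbind(adj[[b]], c(et$edges[i, 1], i))
  }
  label_of <- setNames(names(et$tips), as.character(et$tips))
  is_tip <- function(v) !is.na(label_of[as.character(v)])
  sets <- vector("list", n_e)
  # root at first edge's first endpoint; DFS computing below-sets per edge
  root <- et$edges[1, 1]
  rec <- function(v, from_edge) {
    acc <- character(0)
    if (is_tip(v)) acc <- unname(label_of[as.character(v)])
    nbrs <- adj[[as.character(v)]]
    for (r in seq_len(nrow(nbrs))) {
      ei <- nbrs[r, 2]
      if (!is.na(from_edge) && ei == from_edge) next
      w <- nbrs[r, 1]
      sub <- rec(w, ei)
      sets[[ei]] <<- sub
      acc <- c(acc, sub)
    }
    acc
  }
  rec(root, NA_integer_)
  sets
}

# canonical nontrivial split keys of an etree (block not containing the
# alphabetically first taxon, taxa sorted, joined by ",")
.etree_splits <- function(et) {
  labels <- names(et$tips)
  ref <- min(labels)
  n <- length(labels)
  sets <- .etree_edge_leafsets(et)
  keys <- character(0)
  for (s in sets) {
    if (length(s) < 2 || length(s) > n - 2) next
    blk <- if (ref %in% s) setdiff(labels, s) else s
    keys <- c(keys, paste(sort(blk), collapse = ","))
  }
  unique(keys)
}

.etree_hash <- function(et) {
  paste(c(paste(sort(names(et$tips)), collapse = ","), "|",
          sort(.etree_splits(et))), collapse = ";")
}

# ---- public tree operations ---------------------------------------------

.normalize_tree <- function(phy) {
  phy <- ape::collapse.singles(phy)
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2) phy <- ape::unroot(phy)
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

#' Parse / write Newick trees
#'
#' Thin wrappers over `ape` that normalize to the package's unrooted,
#' branch-length-free convention and optionally validate leaf labels
#' against a character matrix.
#'
#' @param text Newick string (or vector of strings, one tree each).
#' @param matrix optional [char_matrix()]; unknown leaf labels are an error.
#' @return A `phylo` (or list of `phylo` for multiple strings).
#' @export
parse_newick <- function(text, matrix = NULL) {
  one <- function(s) {
    phy <- ape::read.tree(text = s)
    if (is.null(phy)) stop("could not parse Newick: ", s)
    phy <- .normalize_tree(phy)
    if (!is.null(matrix)) {
      bad <- setdiff(phy$tip.label, matrix$taxa)
      if (length(bad)) stop("leaf labels not in matrix: ",
                            paste(bad, collapse = ", "))
    }
    phy
  }
  if (length(text) == 1) one(text) else lapply(text, one)
}

#' @rdname parse_newick
#' @param tree a `phylo`, or list of them.
#' @export
write_newick <- function(tree) {
  if (inherits(tree, "phylo")) return(ape::write.tree(tree))
  vapply(tree, ape::write.tree, "")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge, canonically oriented as the leaf
#' block not containing the alphabetically first leaf, so the set is stable
#' under rerooting and leaf-order permutations.  Two unrooted trees on the
#' same leaves are topologically equal iff their bipartition sets are
#' equal.
#'
#' @param tree a `phylo`.
#' @return A list of character vectors (sorted leaf labels per block), with
#'   the flat keys in `attr(, "keys")`.
#' @export
bipartitions <- function(tree) {
  et <- .phylo_to_etree(tree)
  keys <- sort(.etree_splits(et))
  out <- lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  attr(out, "keys") <- keys
  out
}

.split_key <- function(group, labels) {
  ref <- min(labels)
  blk <- if (ref %in% group) setdiff(labels, group) else group
  paste(sort(blk), collapse = ",")
}

#' Prune taxa from a tree
#'
#' Removes the given leaves and suppresses resulting degree-2 nodes, giving
#' the induced subtree on the remaining taxa (as done a posteriori of a
#' heuristic search when building a reduced consensus).
#'
#' @param tree a `phylo`.
#' @param drop character vector of leaf labels (may be empty).
#' @return The pruned `phylo`.
#' @export
prune_taxa <- function(tree, drop) {
  if (!length(drop)) return(tree)
  bad <- setdiff(drop, tree$tip.label)
  if (length(bad)) stop("cannot prune unknown taxa: ", paste(bad, collapse = ", "))
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < 3) stop("pruning would leave fewer than 3 leaves")
  .normalize_tree(ape::drop.tip(tree, drop))
}

#' All trees one TBR move away
#'
#' Enumerates every distinct topology obtainable by bisecting one branch
#' and reconnecting the two fragments across any pair of their edges.  The
#' input topology is excluded.  TBR generalizes SPR (and NNI), so the
#' returned set contains all SPR neighbors.
#'
#' @param tree a fully resolved `phylo` with >= 4 leaves.
#' @return A list of `phylo` objects, deduplicated by bipartition set.
#' @export
tbr_neighbors <- function(tree) {
  et <- .phylo_to_etree(tree)
  pk <- .dummy_pack(length(et$tips))
  scan <- tbr_scan_cpp(et$edges, unname(et$tips), pk$mask, pk$nstates,
                       pk$ordered, pk$weights, Inf)
  self <- .etree_hash(et)
  seen <- character(0)
  out <- list()
  for (em in scan$kept) {
    nb <- list(edges = em, tips = et$tips)
    h <- .etree_hash(nb)
    if (h == self || h %in% seen) next
    seen <- c(seen, h)
    out[[length(out) + 1L]] <- .etree_to_phylo(nb)
  }
  out
}

# trivial one-character data pack used when only topology matters
.dummy_pack <- function(ntip) {
  list(mask = matrix(1L, ntip, 1), nstates = 1L, ordered = FALSE, weights = 1)
}

# ---- constraints ---------------------------------------------------------

#' Monophyly constraints
#'
#' A constraint is a set of taxon groups plus a mode: `enforce` requires
#' every group to be monophyletic (its bipartition present as an edge of
#' the unrooted tree, with any designated outgroup on the other side);
#' `forbid` is the negation (at least one group non-monophyletic), the form
#' used in reverse-constraint Bremer searches.
#'
#' @param groups a character vector (one group) or list of character
#'   vectors; each group needs at least 2 members.
#' @param mode `"enforce"` or `"forbid"`.
#' @return An object of class `phylo_constraint`.
#' @export
constraint <- function(groups, mode = c("enforce", "forbid")) {
  if (!is.list(groups)) groups <- list(groups)
  for (g in groups) {
    if (length(g) < 2) stop("constraint groups need at least 2 members")
  }
  structure(list(groups = lapply(groups, as.character),
                 mode = match.arg(mode)),
            class = "phylo_constraint")
}

#' Test a tree against a monophyly constraint
#'
#' @param tree a `phylo`.
#' @param constr a [constraint()].
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_constraint <- function(tree, constr) {
  stopifnot(inherits(constr, "phylo_constraint"))
  labels <- tree$tip.label
  keys <- attr(bipartitions(tree), "keys")
  ok <- vapply(constr$groups, function(g) {
    bad <- setdiff(g, labels)
    if (length(bad)) stop("constraint group has unknown taxa: ",
                          paste(bad, collapse = ", "))
    if (length(g) < 2) stop("constraint groups need at least 2 members")
    if (length(g) >= length(labels) - 1) return(TRUE)  # trivial split
    .split_key(g, labels) %in% keys
  }, logical(1))
  if (constr$mode == "enforce") all(ok) else !all(ok)
}

# constraint check on an etree; `partial = TRUE` restricts each group to
# the taxa present and skips groups with < 2 present members (stepwise
# addition cannot repair induced non-monophyly, so this filter is exact)
.etree_satisfies <- function(et, constr, partial = FALSE) {
  labels <- names(et$tips)
  keys <- .etree_splits(et)
  ok <- vapply(constr$groups, function(g) {
    gg <- if (partial) intersect(g, labels) else g
    if (partial && length(gg) < 2) return(TRUE)
    if (!partial && length(setdiff(g, labels))) return(NA)
    if (length(gg) >= length(labels) - 1 || length(gg) < 2) return(TRUE)
    .split_key(gg, labels) %in% keys
  }, logical(1))
  if (anyNA(ok)) stop("constraint group has taxa missing from the tree")
  if (constr$mode == "enforce") all(ok) else !all(ok)
}

# ---- building trees from split sets -------------------------------------

# splits: character vector of canonical keys (see .split_key); must be
# pairwise compatible.  Returns an unrooted, possibly multifurcating phylo.
.tree_from_splits <- function(labels, splits) {
  ref <- min(labels)
  blocks <- lapply(splits, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  blocks <- blocks[order(-lengths(blocks))]
  build <- function(set, cand) {
    inside <- cand[vapply(cand, function(b) all(b %in% set), logical(1))]
    used <- character(0)
    parts <- list()
    for (b in inside) {   # already sorted by decreasing size => maximality
      if (!length(intersect(b, used))) {
        parts[[length(parts) + 1L]] <- b
        used <- c(used, b)
      }
    }
    singles <- setdiff(set, used)
    kids <- c(
      vapply(parts, function(b) {
        sub <- inside[vapply(inside, function(x)
          all(x %in% b) && length(x) < length(b), logical(1))]
        build(b, sub)
      }, ""),
      singles
    )
    paste0("(", paste(kids, collapse = ","), ")")
  }
  txt <- paste0(build(setdiff(labels, ref), blocks), ";")
  # attach reference taxon at the top and unroot
  txt <- sub("^\\(", paste0("(", ref, ",("), txt)
  txt <- sub("\\);$", "));", txt)
  if (length(labels) == 2) txt <- paste0("(", ref, ",", setdiff(labels, ref), ");")
  .normalize_tree(ape::read.tree(text = txt))
}
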