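#' @title Parsimony scoring
#' @description Character and tree lengths under equally weighted (or
#'   user-weighted) parsimony.  Unordered characters cost one step per
#'   state change; ordered (additive) characters cost the state-interval
#'   distance `|i - j|`.  Both are computed exactly by a generalized
#'   Sankoff dynamic program that handles multifurcations and ambiguous
#'   (missing / polymorphic) leaf sets, where ambiguity contributes a free
#'   state choice.
#' @name parsimony
NULL

# raw per-character steps of a phylo on a matrix (active characters only)
.score_phylo <- function(tree, cm, chars = which(cm$active_chars)) {
  et <- .phylo_to_etree(tree)
  pk <- .pack_matrix(cm, taxa = names(et$tips), chars = chars)
  score_edges_cpp(et$edges, unname(et$tips), pk$mask, pk$nstates, pk$ordered)
}

#' Parsimony length of one character
#'
#' @param tree a `phylo` whose leaves are all scored in `matrix`.
#' @param matrix a [char_matrix()].
#' @param char_index 1-based character index.
#' @return Integer number of steps.
#' @examples
#' m <- matrix_from_states(rbind(A = 0, B = 0, C = 1, D = 1))
#' character_length(parse_newick("((A,B),(C,D));"), m, 1)  # 1
#' @export
character_length <- function(tree, matrix, char_index) {
  if (char_index < 1 || char_index > ncol(matrix$cells))
    stop("char_index out of range")
  as.integer(.score_phylo(tree, matrix, chars = as.integer(char_index)))
}

# minimum conceivable steps of character j over all trees and all
# resolutions of ambiguous cells
.min_steps <- function(cm, j) {
  masks <- cm$cells[cm$active_taxa, j]
  k <- cm$nstates[j]
  full <- .full_mask(k)
  masks <- masks[masks != full | k == 1]   # fully ambiguous cells are free
  if (!length(masks)) return(0L)
  if (cm$ordered[j]) {
    los <- vapply(masks, function(m) min(.mask_states(m)), integer(1))
    his <- vapply(masks, function(m) max(.mask_states(m)), integer(1))
    return(max(0L, max(los) - min(his)))
  }
  # unordered: smallest number of states that can cover every cell, minus 1
  sets <- unique(masks)
  best <- k
  # exact search over state subsets, smallest first (k <= 31, but cells
  # restrict the practical alphabet; bound the enumeration by distinct sets)
  cand_states <- sort(unique(unlist(lapply(sets, .mask_states))))
  for (size in seq_along(cand_states)) {
    combos <- utils::combn(cand_states, size, simplify = FALSE)
    hit <- vapply(combos, function(cs) {
      msk <- .bitmask(cs)
      all(bitwAnd(sets, msk) != 0L)
    }, logical(1))
    if (any(hit)) { best <- size; break }
  }
  as.integer(best - 1L)
}

# maximum conceivable steps: length on the star (bush) tree, the worst
# topology, with the best central state
.max_steps <- function(cm, j) {
  masks <- cm$cells[cm$active_taxa, j]
  k <- cm$nstates[j]
  if (cm$ordered[j]) {
    cost <- vapply(0:(k - 1), function(c0) {
      sum(vapply(masks, function(m) {
        s <- .mask_states(m)
        min(abs(s - c0))
      }, numeric(1)))
    }, numeric(1))
  } else {
    cost <- vapply(0:(k - 1), function(c0) {
      sum(vapply(masks, function(m) {
        as.numeric(bitwAnd(m, bitwShiftL(1L, c0)) == 0L)
      }, numeric(1)))
    }, numeric(1))
  }
  as.integer(min(cost))
}

#' Tree length with ensemble indices
#'
#' Computes total length `L` (sum of weighted per-character steps), the
#' minimum `M` and maximum `G` conceivable steps, and the ensemble
#' consistency index `CI = M/L` and retention index `RI = (G-L)/(G-M)`.
#' Indices are reported both over all active characters (the headline
#' values, matching the usual TNT convention) and over
#' parsimony-informative characters only.
#'
#' @inheritParams character_length
#' @return A `length_report` list: `L`, `per_character`, `M`, `G`, `CI`,
#'   `RI`, plus `CI_informative`/`RI_informative`.
#' @export
tree_length <- function(tree, matrix) {
  chars <- which(matrix$active_chars)
  steps <- .score_phylo(tree, matrix, chars)
  w <- matrix$weights[chars]
  L <- sum(w * steps)
  M_per <- vapply(chars, function(j) .min_steps(matrix, j), integer(1))
  G_per <- vapply(chars, function(j) .max_steps(matrix, j), integer(1))
  Mv <- sum(w * M_per); Gv <- sum(w * G_per)
  ci <- if (L > 0) Mv / L else NaN
  ri <- if (Gv > Mv) (Gv - L) / (Gv - Mv) else NaN
  if (L == 0) warning("tree length is 0; CI/RI undefined")
  informative <- M_per < G_per
  Li <- sum((w * steps)[informative])
  Mi <- sum((w * M_per)[informative]); Gi <- sum((w * G_per)[informative])
  per <- setNames(as.integer(steps), chars)
  structure(list(
    L = L, per_character = per, M = Mv, G = Gv, CI = ci, RI = ri,
    CI_informative = if (Li > 0) Mi / Li else NaN,
    RI_informative = if (Gi > Mi) (Gi - Li) / (Gi - Mi) else NaN
  ), class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf("tree length L = %g (M = %g, G = %g)\n", x$L, x$M, x$G))
  cat(sprintf("CI = %.4f, RI = %.4f (all active characters)\n", x$CI, x$RI))
  cat(sprintf("CI = %.4f, RI = %.4f (informative only)\n",
              x$CI_informative, x$RI_informative))
  invisible(x)
}

# ---- MPR machinery (single character, R implementation) -----------------

# min-plus transform across one edge (cost 0/1 or |i-j|)
.transmit <- function(cost, ordered) {
  k <- length(cost)
  if (!ordered || k == 1) return(pmin(cost, min(cost) + 1))
  out <- cost
  for (i in seq_len(k - 1)) out[i + 1] <- min(out[i + 1], out[i] + 1)
  for (i in rev(seq_len(k - 1))) out[i] <- min(out[i], out[i + 1] + 1)
  out
}

# Sankoff down/up pass for one character on a rooted view of `tree`.
# Returns per-node cost vectors: D (subtree below), A (everything outside
# the subtree, seen at the node across its stem edge, edge cost included).
.sankoff_arrays <- function(tree, leaf_masks, k, ordered) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  BIG <- 1e9
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # node postorder via DFS
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    kid_rows <- children[[as.character(v)]]
    if (!is.null(kid_rows)) stack <- c(stack, edge[kid_rows, 2])
  }
  post_nodes <- rev(ord)
  D <- matrix(0, n_node, k)
  for (v in seq_len(n_tip)) {
    D[v, ] <- ifelse(bitwAnd(leaf_masks[v], bitwShiftL(1L, 0:(k - 1))) != 0L, 0, BIG)
  }
  Tm <- matrix(0, n_node, k)  # transmit of D across the node's stem edge
  for (v in post_nodes) {
    kid_rows <- children[[as.character(v)]]
    if (!is.null(kid_rows)) {
      for (r in kid_rows) D[v, ] <- D[v, ] + Tm[edge[r, 2], ]
      D[v, ] <- pmin(D[v, ], BIG)
    }
    Tm[v, ] <- .transmit(D[v, ], ordered)
  }
  A <- matrix(0, n_node, k)
  A[root, ] <- 0
  for (v in ord) {  # preorder
    kid_rows <- children[[as.character(v)]]
    if (is.null(kid_rows)) next
    for (r in kid_rows) {
      w <- edge[r, 2]
      rest <- pmin(A[v, ] + D[v, ] - Tm[w, ], BIG)
      A[w, ] <- .transmit(rest, ordered)
      attr(A, paste0("rest", w)) <- rest
    }
  }
  rests <- lapply(seq_len(n_node), function(w) attr(A, paste0("rest", w)))
  list(D = D, A = A, rest = rests, root = root, edge = edge,
       L = min(D[root, ]))
}

#' Most-parsimonious ancestral state sets (MPR) for one character
#'
#' Two-pass (down/up) dynamic programming giving, at every node, the union
#' of states over all most-parsimonious reconstructions, and a typed change
#' list: an edge's change is `unambiguous` when every MPR places a state
#' change there, `ambiguous` when only some do.
#'
#' @inheritParams character_length
#' @return An `mpr_sets` list: `length`, `node_states` (list of 0-based
#'   state vectors indexed by ape node number), and `changes` (data frame
#'   with `parent`, `child`, `from`, `to`, `status`).
#' @export
ancestral_states <- function(tree, matrix, char_index) {
  if (char_index < 1 || char_index > ncol(matrix$cells))
    stop("char_index out of range")
  k <- matrix$nstates[char_index]
  rows <- match(tree$tip.label, matrix$taxa)
  if (anyNA(rows)) stop("tree has leaves not scored in the matrix")
  leaf_masks <- matrix$cells[rows, char_index]
  .mpr_from_masks(tree, leaf_masks, k, matrix$ordered[char_index])
}

.mpr_from_masks <- function(tree, leaf_masks, k, ordered) {
  sa <- .sankoff_arrays(tree, leaf_masks, k, ordered)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  L <- sa$L
  node_states <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    tot <- if (v == sa$root) sa$D[v, ] else sa$A[v, ] + sa$D[v, ]
    node_states[[v]] <- which(tot <= L + 1e-9) - 1L
  }
  dmat <- if (ordered) abs(outer(0:(k - 1), 0:(k - 1), "-"))
          else 1 - diag(k)
  changes <- NULL
  for (r in seq_len(nrow(sa$edge))) {
    p <- sa$edge[r, 1]; v <- sa$edge[r, 2]
    rest <- sa$rest[[v]]
    pair <- outer(rest, sa$D[v, ], "+") + dmat   # cost by (parent s, child t)
    eq_min <- min(diag(pair) - diag(dmat))       # best with equal endpoints
    ne <- pair; diag(ne) <- Inf
    ne_min <- min(ne)
    status <- if (eq_min > L + 1e-9) "unambiguous"
              else if (ne_min <= L + 1e-9) "ambiguous"
              else "none"
    if (status != "none") {
      opt <- which(ne <= L + 1e-9, arr.ind = TRUE)
      changes <- rbind(changes, data.frame(
        parent = p, child = v,
        from = paste(sort(unique(opt[, 1] - 1L)), collapse = "/"),
        to = paste(sort(unique(opt[, 2] - 1L)), collapse = "/"),
        status = status, terminal = v <= n_tip,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(changes))
    changes <- data.frame(parent = integer(0), child = integer(0),
                          from = character(0), to = character(0),
                          status = character(0), terminal = logical(0))
  structure(list(length = as.integer(round(L)), node_states = node_states,
                 changes = changes, root = sa$root),
            class = "mpr_sets")
}

#' Collapse unsupported (zero-minimum-length) branches
#'
#' Rule-1 collapsing: an internal branch is contracted iff no character
#' forces a state change on it under every most-parsimonious
#' reconstruction, i.e. its minimum optimized length over all MPRs is
#' zero.  Collapsing never changes tree length.
#'
#' @inheritParams character_length
#' @param rule collapsing rule; only `"rule1"` is implemented.
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_zero_length <- function(tree, matrix, rule = "rule1") {
  stopifnot(identical(rule, "rule1"))
  et <- .phylo_to_etree(tree)
  if (length(et$tips) < 4) return(tree)
  pk <- .pack_matrix(cm = matrix, taxa = names(et$tips))
  forced <- forced_changes_cpp(et$edges, unname(et$tips), pk$mask,
                               pk$nstates, pk$ordered)
  is_tip_node <- et$edges[, 2] %in% et$tips
  drop_rows <- which(forced == 0L & !is_tip_node)
  if (!length(drop_rows)) return(tree)
  .contract_edges(et, drop_rows)
}

# contract the given edge rows of an etree (merge endpoints), return phylo
.contract_edges <- function(et, rows) {
  parent_of <- function(x, map) {
    while (!is.null(map[[as.character(x)]])) x <- map[[as.character(x)]]
    x
  }
  map <- list()
  for (r in rows) {
    a <- parent_of(et$edges[r, 1], map)
    b <- parent_of(et$edges[r, 2], map)
    if (a != b) map[[as.character(b)]] <- a
  }
  e2 <- et$edges
  for (i in seq_len(nrow(e2))) {
    e2[i, 1] <- parent_of(e2[i, 1], map)
    e2[i, 2] <- parent_of(e2[i, 2], map)
  }
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  .etree_to_phylo(list(edges = e2, tips = et$tips))
}
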