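#' @title Trait mapping on phylogenies
#' @description Parsimony optimization of discrete traits (e.g. sacral
#'   configuration: S1+S2, DS+S1+S2, DS+S1+S2+CS, ...) and continuous
#'   traits (e.g. femoral lateromedial shaft width, FML, a body-size
#'   proxy) onto trees, plus synapomorphy diagnosis of clades across a
#'   set of optimal trees.
#' @name trait_evolution
NULL

#' Discrete trait
#'
#' @param name trait name.
#' @param values named character vector: taxon -> state label (`NA` =
#'   missing).
#' @param states state label alphabet in index order; defaults to the
#'   sorted unique observed labels.
#' @param ordered treat the trait as ordered/additive.
#' @return A `discrete_trait` list.
#' @export
discrete_trait <- function(name, values, states = NULL, ordered = FALSE) {
  values <- unlist(values)
  if (is.null(states)) states <- sort(unique(values[!is.na(values)]))
  if (anyDuplicated(states)) stop("state labels must be unique")
  bad <- setdiff(values[!is.na(values)], states)
  if (length(bad)) stop("observations outside the state alphabet: ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, values = values, states = states,
                 ordered = ordered), class = "discrete_trait")
}

#' Continuous trait
#'
#' @param name trait name (e.g. `"FML"`).
#' @param values named numeric vector (positive; `NA` = missing).
#' @return A `continuous_trait` list.
#' @export
continuous_trait <- function(name, values) {
  values <- unlist(values)
  if (any(values[!is.na(values)] <= 0))
    stop("continuous trait values must be positive")
  structure(list(name = name, values = values), class = "continuous_trait")
}

#' Map a discrete trait onto a tree
#'
#' MPR-based reconstruction reusing the parsimony machinery: per-node
#' optimal state sets plus a typed change list.  Changes on terminal
#' edges are flagged `autapomorphy`; internal-edge changes present in
#' every MPR are `synapomorphy_unambiguous`, others `ambiguous`.
#'
#' @param tree a `phylo`; leaves without a trait value are treated as
#'   missing.
#' @param trait a [discrete_trait()].
#' @return A `trait_reconstruction` list: `cost`, `node_states` (state
#'   labels per node), `changes` data frame.
#' @export
map_discrete_trait <- function(tree, trait) {
  stopifnot(inherits(trait, "discrete_trait"))
  k <- length(trait$states)
  obs <- trait$values[tree$tip.label]
  if (all(is.na(obs))) stop("all observations missing on this tree")
  masks <- ifelse(is.na(obs), .full_mask(k),
                  bitwShiftL(1L, match(obs, trait$states) - 1L))
  mpr <- .mpr_from_masks(tree, as.integer(masks), k, trait$ordered)
  ch <- mpr$changes
  flag <- ifelse(ch$terminal, "autapomorphy",
                 ifelse(ch$status == "unambiguous",
                        "synapomorphy_unambiguous", "ambiguous"))
  # an ambiguous terminal change is still only a candidate autapomorphy
  flag[ch$terminal & ch$status == "ambiguous"] <- "ambiguous"
  lab <- function(s) paste(trait$states[as.integer(strsplit(s, "/")[[1]]) + 1L],
                           collapse = "/")
  changes <- data.frame(
    parent = ch$parent, child = ch$child,
    from = vapply(ch$from, lab, ""), to = vapply(ch$to, lab, ""),
    flag = flag, stringsAsFactors = FALSE, row.names = NULL)
  node_states <- lapply(mpr$node_states, function(s) trait$states[s + 1L])
  structure(list(trait = trait$name, cost = mpr$length,
                 node_states = node_states, changes = changes),
            class = "trait_reconstruction")
}

#' Synapomorphies diagnosing a clade across optimal trees
#'
#' Lists the characters whose most-parsimonious reconstructions place a
#' change on the clade's stem edge.  A character is `unambiguous` only if
#' the change occurs in every MPR of every supplied tree; a change present
#' in every MPR of some trees but not all (or only in some MPRs) is
#' reported `ambiguous`.
#'
#' @param mpts list of `phylo` (or a `search_result`); the clade must be
#'   monophyletic in each.
#' @param matrix a [char_matrix()].
#' @param clade character vector of taxa.
#' @return Data frame: `character` (1-based index; reports use 1-based
#'   indexing throughout), `from`, `to`, `status`.
#' @export
diagnose_clade <- function(mpts, matrix, clade) {
  trees <- if (inherits(mpts, "search_result")) mpts$trees else mpts
  if (inherits(trees, "phylo")) trees <- list(trees)
  chars <- which(matrix$active_chars)
  status_all <- NULL
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    labels <- tree$tip.label
    key <- .split_key(clade, labels)
    et <- .phylo_to_etree(tree)
    sets <- .etree_edge_leafsets(et)
    hit <- which(vapply(sets, function(s) {
      identical(sort(s), sort(clade)) ||
        identical(sort(s), sort(setdiff(labels, clade)))
    }, logical(1)))
    if (!length(hit))
      stop(sprintf("clade is not monophyletic in tree %d", ti))
    stem_parent <- tree$edge[hit[1], 1]
    stem_child <- tree$edge[hit[1], 2]
    per_char <- lapply(chars, function(j) {
      mpr <- ancestral_states(tree, matrix, j)
      ch <- mpr$changes
      row <- ch[ch$parent == stem_parent & ch$child == stem_child, ,
                drop = FALSE]
      if (!nrow(row)) return(NULL)
      data.frame(character = j, from = row$from[1], to = row$to[1],
                 status = row$status[1], stringsAsFactors = FALSE)
    })
    per_char <- do.call(rbind, per_char)
    if (is.null(per_char))
      per_char <- data.frame(character = integer(0), from = character(0),
                             to = character(0), status = character(0),
                             tree = integer(0))
    else per_char$tree <- ti
    status_all <- rbind(status_all, per_char)
  }
  if (is.null(status_all) || !nrow(status_all))
    return(data.frame(character = integer(0), from = character(0),
                      to = character(0), status = character(0)))
  out <- NULL
  for (j in unique(status_all$character)) {
    sub <- status_all[status_all$character == j, , drop = FALSE]
    unamb <- nrow(sub) == length(trees) && all(sub$status == "unambiguous")
    out <- rbind(out, data.frame(
      character = j, from = sub$from[1], to = sub$to[1],
      status = if (unamb) "unambiguous" else "ambiguous",
      stringsAsFactors = FALSE))
  }
  out[order(out$character), , drop = FALSE]
}

#' Linear-parsimony reconstruction of a continuous trait
#'
#' Minimizes the summed absolute change over the tree (Manhattan cost).
#' Optima of linear parsimony always occur at observed values, so the
#' reconstruction runs the ordered-character dynamic program on the grid
#' of distinct observed values; per-node closed intervals are the union
#' of optimal assignments (Farris intervals).  A squared-change variant
#' (`method = "squared"`), which minimizes summed squared change and
#' yields single values at nodes, is available for comparison.
#'
#' @param tree a `phylo` with at least 2 leaves observed.
#' @param trait a [continuous_trait()].
#' @param method `"linear"` (default) or `"squared"`.
#' @return A `trait_reconstruction` list: `cost`, `node_interval` (2-col
#'   matrix, rows indexed by ape node number).
#' @export
reconstruct_continuous <- function(tree, trait, method = c("linear", "squared")) {
  method <- match.arg(method)
  stopifnot(inherits(trait, "continuous_trait"))
  obs <- trait$values[tree$tip.label]
  if (sum(!is.na(obs)) < 2) stop("need at least 2 observed leaves")
  grid <- sort(unique(obs[!is.na(obs)]))
  k <- length(grid)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (method == "squared") {
    fit <- .squared_change(tree, obs)
    iv <- cbind(fit$states, fit$states)
    return(structure(list(trait = trait$name, cost = fit$cost,
                          node_interval = iv, method = method),
                     class = "trait_reconstruction"))
  }
  BIG <- 1e18
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  root <- setdiff(edge[, 1], edge[, 2])[1]
  ord <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    kid <- children[[as.character(v)]]
    if (!is.null(kid)) stack <- c(stack, edge[kid, 2])
  }
  dmat <- abs(outer(grid, grid, "-"))
  trans <- function(cost) apply(dmat + rep(cost, each = k), 1, min)
  D <- matrix(0, n_node, k)
  for (v in seq_len(n_tip)) {
    D[v, ] <- if (is.na(obs[v])) 0 else ifelse(grid == obs[v], 0, BIG)
  }
  Tm <- matrix(0, n_node, k)
  for (v in rev(ord)) {
    kid <- children[[as.character(v)]]
    if (!is.null(kid)) for (r in kid) D[v, ] <- D[v, ] + Tm[edge[r, 2], ]
    Tm[v, ] <- trans(D[v, ])
  }
  A <- matrix(0, n_node, k)
  for (v in ord) {
    kid <- children[[as.character(v)]]
    if (is.null(kid)) next
    for (r in kid) {
      w <- edge[r, 2]
      rest <- A[v, ] + D[v, ] - Tm[w, ]
      A[w, ] <- trans(rest)
    }
  }
  L <- min(D[root, ])
  iv <- matrix(NA_real_, n_node, 2)
  for (v in seq_len(n_node)) {
    tot <- if (v == root) D[v, ] else A[v, ] + D[v, ]
    opt <- grid[tot <= L + 1e-9]
    iv[v, ] <- range(opt)
  }
  structure(list(trait = trait$name, cost = L, node_interval = iv,
                 method = method),
            class = "trait_reconstruction")
}

# squared-change parsimony: each internal value is the mean of its
# neighbors; solved as a sparse linear system
.squared_change <- function(tree, obs) {
  if (anyNA(obs)) stop("squared-change variant requires fully observed leaves")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  internal <- (n_tip + 1):n_node
  Amat <- matrix(0, length(internal), length(internal))
  bvec <- numeric(length(internal))
  deg <- numeric(n_node)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    for (pr in list(c(a, b), c(b, a))) {
      if (pr[1] > n_tip) {
        i <- pr[1] - n_tip
        if (pr[2] > n_tip) Amat[i, pr[2] - n_tip] <- Amat[i, pr[2] - n_tip] - 1
        else bvec[i] <- bvec[i] + obs[pr[2]]
      }
    }
  }
  diag(Amat) <- deg[internal]
  x <- solve(Amat, bvec)
  states <- c(obs, x)
  cost <- sum((states[edge[, 1]] - states[edge[, 2]])^2)
  list(states = states, cost = cost)
}

#' @export
print.trait_reconstruction <- function(x, ...) {
  cat(sprintf("trait '%s': parsimony cost %g\n", x$trait, x$cost))
  if (!is.null(x$changes) && nrow(x$changes)) {
    cat(sprintf("  %d change(s): %s\n", nrow(x$changes),
                paste(sprintf("%s->%s [%s]", x$changes$from, x$changes$to,
                              x$changes$flag), collapse = "; ")))
  }
  invisible(x)
}
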