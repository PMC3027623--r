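#' @title Consensus trees and branch support
#' @description Strict and reduced strict consensus, greedy identification
#'   of unstable (rogue) taxa with a missing-data vs character-conflict
#'   classification, Bremer supports by reverse-constraint search, and
#'   bootstrap/jackknife resampling summarized as absolute and GC
#'   (group present minus most frequent contradicting group) frequencies.
#' @name support
NULL

.check_same_leaves <- function(trees) {
  sets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(sets)[-1]) {
    if (!identical(sets[[i]], sets[[1]]))
      stop("trees have mismatched leaf sets")
  }
  sets[[1]]
}

#' Strict consensus tree
#'
#' Contains exactly the bipartitions present in every input tree.
#'
#' @param trees a list of `phylo` on identical leaf sets.
#' @return A `phylo`, in general multifurcating.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  labels <- .check_same_leaves(trees)
  keysets <- lapply(trees, function(t) attr(bipartitions(t), "keys"))
  shared <- Reduce(intersect, keysets)
  .tree_from_splits(labels, shared)
}

#' Reduced strict consensus
#'
#' Strict consensus of the input trees after pruning the given taxa a
#' posteriori; equals `strict_consensus(lapply(trees, prune_taxa, prune))`
#' by construction.  Pruning unstable taxa before intersecting typically
#' recovers resolution their floating positions destroy.
#'
#' @inheritParams strict_consensus
#' @param prune character vector of taxa to drop (may be empty).
#' @export
reduced_consensus <- function(trees, prune = character(0)) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(prune)) return(strict_consensus(trees))
  strict_consensus(lapply(trees, prune_taxa, drop = prune))
}

.n_splits <- function(tree) length(attr(bipartitions(tree), "keys"))

# canonical description of where leaf `lab` attaches in `tree`: the
# partition of the remaining leaves induced by its attachment node
.attachment_key <- function(tree, lab) {
  et <- .phylo_to_etree(tree)
  id <- et$tips[[lab]]
  adj <- .etree_adj(et)
  hubs <- adj[[as.character(id)]]
  sets <- .etree_edge_leafsets(et)
  # components around the attachment node, leaf removed
  hub <- hubs[1]
  rows <- which((et$edges[, 1] == hub & et$edges[, 2] != id) |
                (et$edges[, 2] == hub & et$edges[, 1] != id))
  comps <- lapply(rows, function(r) {
    s <- sets[[r]]
    if (lab %in% s) setdiff(setdiff(tree$tip.label, s), lab) else s
  })
  comps <- lapply(comps, sort)
  paste(sort(vapply(comps, paste, "", collapse = ",")), collapse = "|")
}

#' Identify unstable (rogue) taxa
#'
#' Greedy procedure in the spirit of iterative positional congruence
#' pruning: repeatedly find the leaf whose solitary removal most increases
#' the strict-consensus resolution (node count), prune it, and repeat
#' until no removal gains resolution.  For each pruned taxon the
#' alternative attachment positions across the input trees are listed,
#' and - when the matrix is supplied - the instability is classified as
#' `missing_data` if the taxon's scored characters have identical summed
#' optimized length in every alternative position (so only absent data,
#' not conflicting signal, moves it), else `character_conflict`.  This
#' greedy criterion and classifier are a documented stand-in for the full
#' published iterPCR procedure.
#'
#' @param trees list of >= 2 `phylo` on identical leaf sets.
#' @param matrix optional [char_matrix()] used for cause classification.
#' @return An `instability_report` data frame: `taxon`, `gain`,
#'   `n_positions`, `cause`.
#' @export
identify_unstable_taxa <- function(trees, matrix = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 2) stop("need at least 2 trees")
  .check_same_leaves(trees)
  cur <- trees
  pruned <- character(0)
  gains <- integer(0)
  repeat {
    base <- .n_splits(strict_consensus(cur))
    labs <- cur[[1]]$tip.label
    if (length(labs) <= 4) break
    gain <- vapply(labs, function(l) {
      .n_splits(strict_consensus(lapply(cur, prune_taxa, drop = l))) - base
    }, integer(1))
    if (max(gain) <= 0) break
    pick <- sort(labs[gain == max(gain)])[1]
    pruned <- c(pruned, pick)
    gains <- c(gains, max(gain))
    cur <- lapply(cur, prune_taxa, drop = pick)
  }
  n_pos <- integer(length(pruned))
  cause <- rep(NA_character_, length(pruned))
  for (i in seq_along(pruned)) {
    tx <- pruned[i]
    others <- setdiff(pruned, tx)
    base_trees <- if (length(others) &&
                      length(trees[[1]]$tip.label) - length(others) >= 4) {
      lapply(trees, prune_taxa, drop = others)
    } else trees
    keys <- vapply(base_trees, .attachment_key, "", lab = tx)
    uniq <- !duplicated(keys)
    n_pos[i] <- sum(uniq)
    if (!is.null(matrix)) {
      scored <- which(matrix$tag[match(tx, matrix$taxa), ] %in%
                        c("observed", "uncertain") & matrix$active_chars)
      if (!length(scored)) {
        cause[i] <- "missing_data"
      } else {
        lsums <- vapply(base_trees[uniq], function(t)
          sum(.score_phylo(t, matrix, chars = scored) *
                matrix$weights[scored]), numeric(1))
        cause[i] <- if (length(unique(lsums)) == 1) "missing_data"
                    else "character_conflict"
      }
    }
  }
  structure(data.frame(taxon = pruned, gain = gains, n_positions = n_pos,
                       cause = cause, stringsAsFactors = FALSE),
            class = c("instability_report", "data.frame"))
}

# ---- Bremer support ------------------------------------------------------

#' Bremer (decay) supports by reverse-constraint search
#'
#' For every bipartition of the strict consensus of the optimal trees, the
#' Bremer support is the length of the best tree in which the group is
#' *not* monophyletic minus the optimal length.  The default
#' `reverse_constraint` method searches under a forbid-mode constraint per
#' group (exact up to search effort); `suboptimal_sweep` instead retains
#' all trees within `slack` steps of optimum in one search and reads
#' supports off that set, giving lower bounds that may be `NA` when no
#' retained tree contradicts a group.
#'
#' @param matrix a [char_matrix()].
#' @param mpts optimal trees (a `search_result` or list of `phylo`).
#' @param config a [search_config()] controlling per-group search effort.
#' @param method `"reverse_constraint"` or `"suboptimal_sweep"`.
#' @param slack sweep depth (steps above optimum) for the sweep method.
#' @return A `support_table` data frame: `group` (canonical block key) and
#'   `bremer`.
#' @export
bremer_supports <- function(matrix, mpts, config = search_config(n_replicates = 5),
                            method = c("reverse_constraint", "suboptimal_sweep"),
                            slack = 5) {
  method <- match.arg(method)
  trees <- if (inherits(mpts, "search_result")) mpts$trees else mpts
  best <- tree_length(trees[[1]], matrix)$L
  cons <- strict_consensus(trees)
  keys <- attr(bipartitions(cons), "keys")
  bremer <- rep(NA_real_, length(keys))
  if (method == "reverse_constraint") {
    for (i in seq_along(keys)) {
      grp <- strsplit(keys[i], ",", fixed = TRUE)[[1]]
      res <- constrained_search(matrix, constraint(grp, "forbid"), config)
      bremer[i] <- res$best_length - best
    }
  } else {
    config$slack <- slack
    config$collapse <- "none"
    res <- replicated_search(matrix, config)
    lens <- vapply(res$trees, function(t) tree_length(t, matrix)$L, numeric(1))
    for (i in seq_along(keys)) {
      grp <- strsplit(keys[i], ",", fixed = TRUE)[[1]]
      lacks <- vapply(res$trees, function(t)
        !(keys[i] %in% attr(bipartitions(t), "keys")), logical(1))
      if (any(lacks)) bremer[i] <- min(lens[lacks]) - best
    }
  }
  structure(data.frame(group = keys, bremer = bremer,
                       stringsAsFactors = FALSE),
            class = c("support_table", "data.frame"))
}

# ---- resampling ----------------------------------------------------------

.splits_compatible <- function(a, b, labels) {
  ga <- strsplit(a, ",", fixed = TRUE)[[1]]
  gb <- strsplit(b, ",", fixed = TRUE)[[1]]
  int <- intersect(ga, gb)
  if (!length(int)) return(TRUE)
  if (all(ga %in% gb) || all(gb %in% ga)) return(TRUE)
  length(union(ga, gb)) == length(labels)
}

#' Bootstrap / jackknife group frequencies
#'
#' Characters are resampled (bootstrap: with replacement to the original
#' count; jackknife: independent deletion with probability `p_del`), each
#' pseudoreplicate is searched at reduced effort, and the bipartitions of
#' its strict consensus are tallied.  `absolute` is the percentage of
#' pseudoreplicates recovering a group; `GC` subtracts the frequency of
#' the most frequent contradicting group, so it ranges from -100 (always
#' contradicted) to 100 (always recovered, never contradicted).
#'
#' @param matrix a [char_matrix()].
#' @param config a [search_config()] for the per-pseudoreplicate search
#'   (keep the effort modest).
#' @param scheme `"bootstrap"` or `"jackknife"`.
#' @param n_reps number of pseudoreplicates.
#' @param groups bipartition keys to report; defaults to the strict
#'   consensus groups of a search on the original matrix (or supply
#'   `mpts`).
#' @param mpts optional optimal trees defining the reported groups.
#' @param p_del jackknife per-character deletion probability (the common
#'   default 0.36, approximately `1 - exp(-1)`).
#' @return A `support_table` data frame: `group`, `absolute`, `gc`.
#' @export
resampling_support <- function(matrix, config = search_config(n_replicates = 3,
                                                              hold = 5),
                               scheme = c("bootstrap", "jackknife"),
                               n_reps = 100, groups = NULL, mpts = NULL,
                               p_del = 0.36) {
  scheme <- match.arg(scheme)
  stopifnot(n_reps >= 1)
  if (is.null(groups)) {
    if (is.null(mpts)) mpts <- replicated_search(matrix, config)
    trees <- if (inherits(mpts, "search_result")) mpts$trees else mpts
    groups <- attr(bipartitions(strict_consensus(trees)), "keys")
  }
  labels <- matrix$taxa[matrix$active_taxa]
  seeds <- .derive_seeds(config$seed, n_reps)
  tally <- new.env(parent = emptyenv())
  per_rep <- vector("list", n_reps)
  base_w <- matrix$weights
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    nc <- ncol(matrix$cells)
    w <- if (scheme == "bootstrap") {
      as.numeric(tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc))
    } else {
      as.numeric(runif(nc) >= p_del)
    }
    m2 <- matrix
    m2$weights <- base_w * w
    m2$active_chars <- matrix$active_chars & w > 0
    if (!any(m2$active_chars)) { per_rep[[r]] <- character(0); next }
    cfg <- config
    cfg$seed <- seeds[r]
    cfg$collapse <- "none"
    res <- replicated_search(m2, cfg)
    ks <- attr(bipartitions(strict_consensus(res$trees)), "keys")
    per_rep[[r]] <- ks
    for (k in ks) assign(k, (if (exists(k, tally)) get(k, tally) else 0) + 1,
                         tally)
  }
  all_keys <- ls(tally)
  all_freq <- vapply(all_keys, function(k) get(k, tally), numeric(1)) /
    n_reps * 100
  absolute <- vapply(groups, function(g)
    100 * mean(vapply(per_rep, function(ks) g %in% ks, logical(1))), numeric(1))
  gc <- vapply(seq_along(groups), function(i) {
    contra <- all_keys[!vapply(all_keys, .splits_compatible, logical(1),
                               b = groups[i], labels = labels)]
    worst <- if (length(contra)) max(all_freq[contra]) else 0
    absolute[i] - worst
  }, numeric(1))
  structure(data.frame(group = groups, absolute = absolute, gc = gc,
                       stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("support_table", "data.frame"))
}
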