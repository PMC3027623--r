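#' @title Heuristic parsimony tree search
#' @description The classic two-stage strategy: many replicates of
#'   random-addition-sequence Wagner trees, each refined by TBR branch
#'   swapping while holding a bounded buffer of equally parsimonious
#'   trees, then a final unbounded round of TBR over the pooled best trees
#'   to expand the full optimal set.  All randomness flows from one master
#'   seed, so runs are exactly reproducible.
#' @name search
NULL

#' Search configuration
#'
#' @param n_replicates number of random-addition + TBR replicates.
#' @param hold maximum equally parsimonious trees held per replicate.
#' @param final_buffer_limit cap on the final-round tree buffer
#'   (`Inf` = unbounded).
#' @param seed master seed; each replicate derives its own stream.
#' @param collapse collapse rule applied to the final tree set
#'   (`"rule1"` or `"none"`).
#' @param constraint optional [constraint()].
#' @param slack retain trees up to `slack` steps above the best
#'   (suboptimal mode; 0 = optimal only).
#' @return A `search_config` list.
#' @export
search_config <- function(n_replicates = 10, hold = 10,
                          final_buffer_limit = Inf, seed = NULL,
                          collapse = "rule1", constraint = NULL,
                          slack = 0) {
  stopifnot(n_replicates >= 1, hold >= 1, slack >= 0)
  structure(list(n_replicates = as.integer(n_replicates),
                 hold = as.integer(hold),
                 final_buffer_limit = final_buffer_limit,
                 seed = seed, collapse = collapse,
                 constraint = constraint, slack = slack),
            class = "search_config")
}

# ---- Wagner addition -----------------------------------------------------

.star3 <- function(labels, ids, hub) {
  list(edges = cbind(rep(hub, 3L), ids), tips = setNames(ids, labels))
}

# attach tip (id, label) onto edge row r of et, subdividing it
.attach_tip <- function(et, r, id, label, new_node) {
  a <- et$edges[r, 1]; b <- et$edges[r, 2]
  e2 <- rbind(et$edges[-r, , drop = FALSE],
              c(a, new_node), c(new_node, b), c(new_node, id))
  list(edges = e2, tips = c(et$tips, setNames(id, label)))
}

#' Random-addition-sequence Wagner tree
#'
#' Taxa are added in seeded random order, each at the insertion edge that
#' minimizes current tree length (ties broken uniformly at random from the
#' same stream).  With a constraint, only placements keeping every
#' constraint group's present members monophyletic are considered.
#'
#' @param matrix a [char_matrix()] with at least 4 active taxa.
#' @param seed integer seed for the addition sequence.
#' @param constraint optional [constraint()] (enforce mode is filtered
#'   during addition; forbid mode is enforced afterwards by the caller).
#' @return A `phylo`.
#' @export
random_addition_wagner <- function(matrix, seed = NULL, constraint = NULL) {
  et <- .wagner_etree(matrix, seed, constraint)
  .etree_to_phylo(et)
}

.wagner_etree <- function(cm, seed = NULL, constraint = NULL) {
  taxa <- cm$taxa[cm$active_taxa]
  if (length(taxa) < 4) stop("need at least 4 active taxa for tree search")
  if (!is.null(seed)) set.seed(seed)
  ord <- sample(taxa)
  pk <- .pack_matrix(cm, taxa = taxa)
  pk$taxa_present <- NULL
  ids <- seq_along(taxa)
  et <- .star3(ord[1:3], ids[match(ord[1:3], taxa)], hub = length(taxa) + 1L)
  enforce <- !is.null(constraint) && constraint$mode == "enforce"
  for (i in 4:length(ord)) {
    lab <- ord[i]
    id <- ids[match(lab, taxa)]
    new_node <- max(et$edges, id) + 1L
    cand <- lapply(seq_len(nrow(et$edges)), function(r)
      .attach_tip(et, r, id, lab, new_node))
    if (enforce) {
      ok <- vapply(cand, .etree_satisfies, logical(1),
                   constr = constraint, partial = TRUE)
      if (!any(ok)) stop("constraint unsatisfiable during Wagner addition")
      cand <- cand[ok]
    }
    lens <- vapply(cand, function(x) {
      present <- names(x$tips)
      steps <- score_edges_cpp(x$edges, unname(x$tips),
                               pk$mask[match(present, taxa), , drop = FALSE],
                               pk$nstates, pk$ordered)
      sum(steps * pk$weights)
    }, numeric(1))
    best <- which(lens == min(lens))
    pick <- if (length(best) == 1) best else sample(best, 1)
    et <- cand[[pick]]
  }
  et
}

# ---- TBR swapping --------------------------------------------------------

# core driver over etrees; returns list(best, trees = list of etrees)
.tbr_drive <- function(start_ets, cm, hold = 10, slack = 0,
                       constraint = NULL, max_sweeps = Inf) {
  taxa <- names(start_ets[[1]]$tips)
  pk <- .pack_matrix(cm, taxa = taxa)
  tid <- function(et) unname(et$tips[taxa])  # data-row-aligned tip ids
  lens0 <- vapply(start_ets, function(et) {
    sum(score_edges_cpp(et$edges, tid(et), pk$mask, pk$nstates,
                        pk$ordered) * pk$weights)
  }, numeric(1))
  sat <- function(et) is.null(constraint) || .etree_satisfies(et, constraint)
  sat0 <- vapply(start_ets, sat, logical(1))
  if (!any(sat0)) {
    # repair: find a constraint-satisfying tree via one TBR scan from the
    # best start (always possible for satisfiable constraints in practice)
    et <- start_ets[[which.min(lens0)]]
    scan <- tbr_scan_cpp(et$edges, tid(et), pk$mask, pk$nstates,
                         pk$ordered, pk$weights, Inf)
    keep <- NULL; keep_len <- Inf
    for (i in seq_along(scan$kept)) {
      nb <- list(edges = scan$kept[[i]], tips = et$tips)
      if (scan$kept_len[i] < keep_len && sat(nb)) {
        keep <- nb; keep_len <- scan$kept_len[i]
      }
    }
    if (is.null(keep)) stop("constraint appears unsatisfiable from this start")
    start_ets <- list(keep); lens0 <- keep_len; sat0 <- TRUE
  } else {
    start_ets <- start_ets[sat0]
    lens0 <- lens0[sat0]
  }
  best <- min(lens0)
  buffer <- list(); hashes <- character(0); swapped <- logical(0)
  blens <- numeric(0)
  add_tree <- function(et, len) {
    h <- .etree_hash(et)
    if (h %in% hashes) return(FALSE)
    buffer[[length(buffer) + 1L]] <<- et
    hashes <<- c(hashes, h)
    swapped <<- c(swapped, FALSE)
    blens <<- c(blens, len)
    TRUE
  }
  for (i in seq_along(start_ets)) add_tree(start_ets[[i]], lens0[i])
  sweeps <- 0
  repeat {
    todo <- which(!swapped & blens <= best + slack)
    if (!length(todo) || sweeps >= max_sweeps) break
    i <- todo[1]
    swapped[i] <- TRUE
    sweeps <- sweeps + 1
    et <- buffer[[i]]
    scan <- tbr_scan_cpp(et$edges, tid(et), pk$mask, pk$nstates,
                         pk$ordered, pk$weights, best + slack)
    improved <- FALSE
    for (jj in seq_along(scan$kept)) {
      len <- scan$kept_len[jj]
      nb <- list(edges = scan$kept[[jj]], tips = et$tips)
      if (!sat(nb)) next
      if (len < best) {
        # new optimum: restart the buffer around it
        best <- len
        keepi <- which(blens <= best + slack)
        buffer <- buffer[keepi]; hashes <- hashes[keepi]
        swapped <- swapped[keepi]; blens <- blens[keepi]
        add_tree(nb, len)
        improved <- TRUE
      } else if (len <= best + slack && length(buffer) < hold) {
        add_tree(nb, len)
      }
    }
    if (improved) next
  }
  keepi <- which(blens <= best + slack)
  list(best = best, trees = buffer[keepi], lens = blens[keepi])
}

#' TBR branch swapping from a set of starting trees
#'
#' Hill-climbs by tree bisection and reconnection, accepting strict
#' improvements and exploring equal-length (or within-`slack`) plateaus up
#' to the buffer limit; finishes when every buffered tree has been swapped
#' without improvement.  In constrained mode only constraint-satisfying
#' rearrangements are accepted.
#'
#' @param start a `phylo` or list of `phylo` starting trees.
#' @param matrix a [char_matrix()].
#' @param config a [search_config()]; `hold` bounds the buffer, `slack`
#'   retains suboptimal trees.
#' @return A `search_result`: `best_length`, `trees` (deduplicated), and
#'   per-tree lengths.
#' @export
tbr_search <- function(start, matrix, config = search_config()) {
  if (inherits(start, "phylo")) start <- list(start)
  ets <- lapply(start, .phylo_to_etree)
  res <- .tbr_drive(ets, matrix, hold = config$hold, slack = config$slack,
                    constraint = config$constraint)
  .as_search_result(res, matrix, config, replicate_hits = NA_integer_,
                    log = res$best)
}

.as_search_result <- function(res, cm, config, replicate_hits, log) {
  trees <- res$trees
  lens <- res$lens
  if (identical(config$collapse, "rule1")) {
    phys <- lapply(trees, function(et)
      collapse_zero_length(.etree_to_phylo(et), cm))
  } else {
    phys <- lapply(trees, .etree_to_phylo)
  }
  keys <- vapply(phys, function(p) .etree_hash(.phylo_to_etree(p)), "")
  keep <- !duplicated(keys)
  structure(list(best_length = min(res$best, min(lens)),
                 trees = phys[keep], tree_lengths = lens[keep],
                 replicate_hits = replicate_hits, log = log),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: best length %g, %d distinct trees\n",
              x$best_length, length(x$trees)))
  if (!is.na(x$replicate_hits))
    cat(sprintf("  best length found in %d/%d replicates\n",
                x$replicate_hits, length(x$log)))
  invisible(x)
}

#' Replicated random-addition + TBR search
#'
#' Runs `n_replicates` independent Wagner + TBR rounds (each holding
#' `hold` trees), pools the per-replicate best trees, and subjects them to
#' a final round of TBR branch swapping with an unbounded (or capped)
#' buffer to expand the full set of optimal trees.  Output trees are
#' collapsed by rule 1 and deduplicated by bipartition set.
#'
#' @param matrix a [char_matrix()].
#' @param config a [search_config()].
#' @return A `search_result` with `replicate_hits` (replicates whose best
#'   equals the overall best) and the per-replicate length `log`.
#' @export
replicated_search <- function(matrix, config = search_config()) {
  seeds <- .derive_seeds(config$seed, config$n_replicates)
  pool <- list(); pool_lens <- numeric(0)
  rep_best <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    et0 <- .wagner_etree(matrix, seed = seeds[r], constraint = config$constraint)
    res <- .tbr_drive(list(et0), matrix, hold = config$hold, slack = 0,
                      constraint = config$constraint)
    rep_best[r] <- res$best
    pool <- c(pool, res$trees)
    pool_lens <- c(pool_lens, res$lens)
  }
  best <- min(rep_best)
  keep <- pool_lens <= best
  pool <- pool[keep]
  # final unbounded round over the pooled best trees
  final <- .tbr_drive(pool, matrix,
                      hold = if (is.finite(config$final_buffer_limit))
                        config$final_buffer_limit else .Machine$integer.max,
                      slack = config$slack, constraint = config$constraint)
  hits <- sum(rep_best == final$best)
  .as_search_result(final, matrix, config, replicate_hits = hits,
                    log = rep_best)
}

#' Parsimony search under a monophyly constraint
#'
#' Convenience wrapper running [replicated_search()] with the constraint
#' installed; used for topology hypothesis tests (enforce mode) and
#' reverse-constraint Bremer supports (forbid mode).  The constrained
#' optimum is never shorter than the unconstrained one.
#'
#' @inheritParams replicated_search
#' @param constr a [constraint()].
#' @return A `search_result`.
#' @export
constrained_search <- function(matrix, constr, config = search_config()) {
  config$constraint <- constr
  replicated_search(matrix, config)
}
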