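#' Analysis configuration
#'
#' Bundles everything [run_full_analysis()] needs: the matrix, search
#' settings, the a-posteriori prune list for the reduced consensus,
#' named constraint hypotheses to test (each searched under enforcement
#' and compared to the optimal trees with extra steps and a Templeton
#' test), resampling settings, optional trait tables, and a master seed.
#'
#' @param matrix a [char_matrix()] or path to a NEXUS/TNT file.
#' @param outgroup outgroup taxon label (display rooting only).
#' @param search a [search_config()].
#' @param prune taxa to prune for the reduced consensus (default: taken
#'   from the instability report).
#' @param hypotheses named list of [constraint()] objects (enforce mode)
#'   describing alternative placements to test.
#' @param resampling list with `n_reps`, `schemes` (subset of
#'   `c("bootstrap","jackknife")`), and `config` for pseudoreplicate
#'   searches; `NULL` disables resampling.
#' @param bremer logical: compute Bremer supports.
#' @param traits list of [discrete_trait()] / [continuous_trait()] to map
#'   on the strict consensus (discrete) and first MPT (continuous).
#' @param output_dir directory for report artifacts (`NULL` = in-memory
#'   only).
#' @param seed master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(matrix, outgroup = NULL,
                            search = search_config(),
                            prune = NULL, hypotheses = list(),
                            resampling = NULL, bremer = TRUE,
                            traits = list(), output_dir = NULL,
                            seed = 1) {
  if (is.character(matrix)) matrix <- read_matrix(matrix)
  stopifnot(inherits(matrix, "char_matrix"))
  if (!is.null(prune)) {
    bad <- setdiff(prune, matrix$taxa)
    if (length(bad)) stop("prune list has unknown taxa: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(matrix = matrix, outgroup = outgroup, search = search,
                 prune = prune, hypotheses = hypotheses,
                 resampling = resampling, bremer = bremer, traits = traits,
                 output_dir = output_dir, seed = seed),
            class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full parsimony analysis pipeline
#'
#' Executes, in order: replicated heuristic search (collapse + dedup),
#' strict consensus, instability report, reduced strict consensus,
#' Bremer supports, bootstrap/jackknife resampling (absolute and GC
#' frequencies), each constrained hypothesis search with its extra-step
#' count and Templeton test, and trait mappings.  All randomness derives
#' from the master seed, so reruns are bit-identical.
#'
#' @param config an [analysis_config()].
#' @return A `report` list (also written as JSON/TSV/Newick artifacts if
#'   `output_dir` is set).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cm <- config$matrix
  seeds <- .derive_seeds(config$seed, 4 + length(config$hypotheses))
  scfg <- config$search
  scfg$seed <- seeds[1]

  res <- .stage("search", replicated_search(cm, scfg))
  lr <- .stage("scoring", tree_length(res$trees[[1]], cm))
  cons <- .stage("consensus", strict_consensus(res$trees))

  instab <- NULL
  if (length(res$trees) >= 2)
    instab <- .stage("instability", identify_unstable_taxa(res$trees, cm))
  prune <- config$prune
  if (is.null(prune)) prune <- if (!is.null(instab)) instab$taxon else character(0)
  reduced <- if (length(prune))
    .stage("reduced_consensus", reduced_consensus(res$trees, prune)) else cons

  brem <- NULL
  if (isTRUE(config$bremer)) {
    bcfg <- search_config(n_replicates = 3, hold = scfg$hold, seed = seeds[2])
    brem <- .stage("bremer", bremer_supports(cm, res, bcfg))
  }

  resamp <- list()
  if (!is.null(config$resampling)) {
    rs <- config$resampling
    rcfg <- rs$config %||% search_config(n_replicates = 2, hold = 5)
    rcfg$seed <- seeds[3]
    for (sch in rs$schemes %||% c("bootstrap", "jackknife")) {
      resamp[[sch]] <- .stage(paste0("resampling_", sch),
        resampling_support(cm, rcfg, scheme = sch,
                           n_reps = rs$n_reps %||% 100, mpts = res))
    }
  }

  hyp <- list()
  for (i in seq_along(config$hypotheses)) {
    nm <- names(config$hypotheses)[i]
    constr <- config$hypotheses[[i]]
    hcfg <- search_config(n_replicates = scfg$n_replicates, hold = scfg$hold,
                          seed = seeds[3 + i])
    hres <- .stage(paste0("hypothesis_", nm),
                   constrained_search(cm, constr, hcfg))
    tt <- .stage(paste0("templeton_", nm),
                 templeton_test(cm, res$trees[[1]], hres$trees[[1]]))
    hyp[[nm]] <- list(extra_steps = hres$best_length - res$best_length,
                      templeton_p = tt$p, templeton_N = tt$N,
                      best_tree = hres$trees[[1]])
  }

  traits <- list()
  for (tr in config$traits) {
    if (inherits(tr, "discrete_trait")) {
      traits[[tr$name]] <- .stage(paste0("trait_", tr$name),
                                  map_discrete_trait(res$trees[[1]], tr))
    } else if (inherits(tr, "continuous_trait")) {
      traits[[tr$name]] <- .stage(paste0("trait_", tr$name),
                                  reconstruct_continuous(res$trees[[1]], tr))
    }
  }

  report <- list(
    n_taxa = sum(cm$active_taxa),
    n_characters = sum(cm$active_chars),
    best_length = res$best_length,
    CI = lr$CI, RI = lr$RI,
    n_mpts = length(res$trees),
    replicate_hits = res$replicate_hits,
    n_replicates = length(res$log),
    consensus = write_newick(cons),
    reduced_consensus = write_newick(reduced),
    pruned_taxa = prune,
    instability = instab,
    bremer = brem,
    resampling = lapply(resamp, function(x) x),
    hypotheses = lapply(hyp, function(h)
      h[c("extra_steps", "templeton_p", "templeton_N")]),
    traits = lapply(traits, function(x)
      list(cost = x$cost, changes = x$changes)),
    seed = config$seed
  )
  if (!is.null(config$output_dir)) .write_report(report, res, config)
  structure(c(report, list(mpts = res$trees)), class = "parsimony_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_report <- function(report, res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  writeLines(vapply(res$trees, ape::write.tree, ""), p("mpts.nwk"))
  writeLines(report$consensus, p("consensus.nwk"))
  writeLines(report$reduced_consensus, p("reduced_consensus.nwk"))
  if (!is.null(report$bremer))
    utils::write.table(report$bremer, p("bremer.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  for (nm in names(report$resampling))
    utils::write.table(report$resampling[[nm]], p(paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  json <- report
  json$instability <- if (!is.null(report$instability))
    as.data.frame(report$instability) else NULL
  json$bremer <- if (!is.null(report$bremer)) as.data.frame(report$bremer)
    else NULL
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(NULL)
}

#' @export
print.parsimony_report <- function(x, ...) {
  cat(sprintf("parsimony analysis: %d taxa x %d characters\n",
              x$n_taxa, x$n_characters))
  cat(sprintf("  best length %g (CI %.3f, RI %.3f), %d MPTs; best found in %d/%d replicates\n",
              x$best_length, x$CI, x$RI, x$n_mpts, x$replicate_hits,
              x$n_replicates))
  if (length(x$pruned_taxa))
    cat("  pruned for reduced consensus:",
        paste(x$pruned_taxa, collapse = ", "), "\n")
  for (nm in names(x$hypotheses)) {
    h <- x$hypotheses[[nm]]
    cat(sprintf("  hypothesis '%s': +%g steps, Templeton p = %.4g\n",
                nm, h$extra_steps, h$templeton_p))
  }
  invisible(x)
}
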