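#' Templeton (Wilcoxon signed-rank) test of two topologies
#'
#' Compares the per-character parsimony lengths of two trees on the same
#' matrix.  Characters with equal length on both trees are dropped;
#' absolute differences are ranked with midranks for ties; the test
#' statistic is the smaller of the two signed rank sums.  For `N <= 25`
#' nonzero differences the two-tailed p-value comes from the exact
#' distribution of the rank sum over all sign assignments (computed by
#' dynamic programming on the doubled, integer-valued midranks); for
#' larger `N` a normal approximation with tie correction and continuity
#' correction is used.  Both branches are exposed through `variant`.
#'
#' @param matrix a [char_matrix()].
#' @param tree_a,tree_b `phylo` trees on the full active taxon set.
#' @param variant `"auto"` (exact for `N <= 25`), `"exact"`, or
#'   `"normal"`.
#' @return A `templeton_test` list: per-character `diffs`, `N`, rank sums
#'   `R_plus`/`R_minus`, `T_stat`, `z` (normal branch), two-tailed `p`,
#'   and `identical` (TRUE when no character distinguishes the trees, in
#'   which case p = 1).
#' @examples
#' m <- matrix_from_states(rbind(A = c(0, 0, 0), B = c(0, 1, 1),
#'                               C = c(1, 0, 1), D = c(1, 1, 0)))
#' t1 <- parse_newick("((A,B),(C,D));")
#' t2 <- parse_newick("((A,C),(B,D));")
#' templeton_test(m, t1, t2)$p   # 1: one character each way
#' @export
templeton_test <- function(matrix, tree_a, tree_b,
                           variant = c("auto", "exact", "normal")) {
  variant <- match.arg(variant)
  active <- sort(matrix$taxa[matrix$active_taxa])
  if (!identical(sort(tree_a$tip.label), active) ||
      !identical(sort(tree_b$tip.label), active))
    stop("both trees must span the full active taxon set")
  chars <- which(matrix$active_chars)
  la <- .score_phylo(tree_a, matrix, chars)
  lb <- .score_phylo(tree_b, matrix, chars)
  d <- as.numeric(la - lb)
  nz <- which(d != 0)
  N <- length(nz)
  if (N == 0) {
    return(structure(list(diffs = setNames(d, chars), N = 0L,
                          R_plus = 0, R_minus = 0, T_stat = 0,
                          z = NA_real_, p = 1, identical = TRUE,
                          method = "degenerate"),
                     class = "templeton_test"))
  }
  ad <- abs(d[nz])
  rk <- rank(ad)
  R_plus <- sum(rk[d[nz] > 0])
  R_minus <- sum(rk[d[nz] < 0])
  T_stat <- min(R_plus, R_minus)
  use_exact <- switch(variant, auto = N <= 25, exact = TRUE, normal = FALSE)
  if (use_exact) {
    p <- .signed_rank_exact_p(rk, T_stat)
    z <- NA_real_
    method <- "exact"
  } else {
    n <- N
    z0 <- R_plus - n * (n + 1) / 4
    ties <- table(rk)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    z <- (z0 - sign(z0) * 0.5) / sigma
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal"
  }
  structure(list(diffs = setNames(d, chars), N = as.integer(N),
                 R_plus = R_plus, R_minus = R_minus, T_stat = T_stat,
                 z = z, p = p, identical = FALSE, method = method),
            class = "templeton_test")
}

# exact two-tailed p of the signed-rank statistic for arbitrary midranks:
# distribution of R+ over the 2^N equiprobable sign assignments, by
# convolution over doubled (hence integer) ranks
.signed_rank_exact_p <- function(ranks, T_stat) {
  r2 <- as.integer(round(2 * ranks))
  S2 <- sum(r2)
  dist <- numeric(S2 + 1)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(S2 + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  t2 <- round(2 * T_stat)
  lower <- sum(dist[seq_len(min(t2 + 1, S2 + 1))])
  upper <- sum(dist[(S2 + 1 - t2):(S2 + 1)])
  min(1, lower + upper)
}

#' @export
print.templeton_test <- function(x, ...) {
  if (x$identical) {
    cat("Templeton test: trees are score-identical per character; p = 1\n")
  } else {
    cat(sprintf("Templeton test (%s): N = %d, T = %g (R+ = %g, R- = %g), p = %.4g\n",
                x$method, x$N, x$T_stat, x$R_plus, x$R_minus, x$p))
  }
  invisible(x)
}
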