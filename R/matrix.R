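#' Discrete character matrix
#'
#' The container all parsimony scoring operates on: an ordered set of taxa,
#' an ordered set of characters (unordered or ordered/additive), and a
#' rectangular grid of cell state sets.  Cells are stored as integer
#' bitmasks (bit *j* set means state *j* is compatible with the
#' observation), with a parallel tag matrix recording whether each cell was
#' observed, missing (`?`), a gap/inapplicable (`-`), or an uncertain /
#' polymorphic set.  Missing and gap cells carry the full state alphabet of
#' their character, so they contribute a free state choice during
#' optimization.
#'
#' @param cells integer matrix of state bitmasks, taxa in rows.
#' @param taxa character vector of unique, non-empty taxon labels.
#' @param tag character matrix of cell tags (`"observed"`, `"missing"`,
#'   `"gap"`, `"uncertain"`); defaults are inferred from `cells`.
#' @param ordered logical vector, one per character: treat the character as
#'   ordered (additive, cost `|i - j|`) rather than unordered (cost 0/1).
#' @param nstates integer vector: alphabet size per character.  Defaults to
#'   the highest state present in each column plus one.
#' @param weights numeric vector of non-negative character weights
#'   (1 = equal weighting).
#' @param active_taxa,active_chars logical vectors marking rows/columns that
#'   participate in searches.
#' @param symbols state symbol table used for I/O.
#' @return An object of class `char_matrix`.
#' @seealso [read_matrix()], [matrix_summary()], [tree_length()]
#' @export
char_matrix <- function(cells, taxa, tag = NULL, ordered = FALSE,
                        nstates = NULL, weights = 1,
                        active_taxa = TRUE, active_chars = TRUE,
                        symbols = .parsikit_symbols) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  nt <- nrow(cells)
  nc <- ncol(cells)
  taxa <- as.character(taxa)
  if (length(taxa) != nt) stop("length(taxa) must equal nrow(cells)")
  if (anyDuplicated(taxa)) stop("taxon names must be unique")
  if (any(!nzchar(taxa))) stop("taxon names must be non-empty")
  if (nc < 1) stop("a character matrix needs at least one character")
  if (is.null(nstates)) {
    nstates <- vapply(seq_len(nc), function(j) {
      mx <- max(vapply(cells[, j], function(m) {
        s <- .mask_states(m)
        if (length(s)) max(s) else -1L
      }, integer(1)))
      max(mx + 1L, 1L)
    }, integer(1))
  }
  nstates <- as.integer(rep_len(nstates, nc))
  if (any(nstates < 1L)) stop("n_states must be >= 1")
  if (any(nstates > 31L)) stop("at most 31 states per character are supported")
  ordered <- rep_len(as.logical(ordered), nc)
  weights <- rep_len(as.numeric(weights), nc)
  if (any(weights < 0)) stop("character weights must be non-negative")
  for (j in seq_len(nc)) {
    if (any(cells[, j] <= 0L)) stop("every cell must allow at least one state")
    if (any(cells[, j] > .full_mask(nstates[j])))
      stop(sprintf("character %d has a state outside its %d-state alphabet",
                   j, nstates[j]))
  }
  if (is.null(tag)) {
    tag <- matrix("observed", nt, nc)
    for (j in seq_len(nc)) {
      full <- .full_mask(nstates[j])
      multi <- vapply(cells[, j], function(m) length(.mask_states(m)) > 1L,
                      logical(1))
      tag[cells[, j] == full & nstates[j] > 1L, j] <- "missing"
      tag[multi & cells[, j] != full, j] <- "uncertain"
    }
  }
  structure(list(
    taxa = taxa, cells = cells, tag = tag, ordered = ordered,
    nstates = nstates, weights = weights,
    active_taxa = rep_len(as.logical(active_taxa), nt),
    active_chars = rep_len(as.logical(active_chars), nc),
    symbols = symbols
  ), class = "char_matrix")
}

#' Build a character matrix from singleton observed states
#'
#' Convenience constructor used by the simulator and in tests: `states` is
#' an integer matrix of 0-based observed states with `NA` for missing.
#'
#' @param states integer matrix (taxa x characters), `NA` = missing.
#' @param taxa taxon labels; defaults to rownames.
#' @inheritParams char_matrix
#' @return A `char_matrix`.
#' @export
matrix_from_states <- function(states, taxa = rownames(states),
                               ordered = FALSE, nstates = NULL, weights = 1) {
  states <- as.matrix(states)
  nc <- ncol(states)
  if (is.null(nstates)) {
    nstates <- vapply(seq_len(nc), function(j) {
      v <- states[, j]
      if (all(is.na(v))) 1L else as.integer(max(v, na.rm = TRUE)) + 1L
    }, integer(1))
  }
  nstates <- as.integer(rep_len(nstates, nc))
  cells <- states
  tag <- matrix("observed", nrow(states), nc)
  for (j in seq_len(nc)) {
    full <- .full_mask(nstates[j])
    cells[, j] <- ifelse(is.na(states[, j]), full,
                         bitwShiftL(1L, as.integer(states[, j])))
    tag[is.na(states[, j]), j] <- "missing"
  }
  storage.mode(cells) <- "integer"
  char_matrix(cells, taxa = taxa, tag = tag, ordered = ordered,
              nstates = nstates, weights = weights)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%d ordered)\n",
              length(x$taxa), ncol(x$cells), sum(x$ordered)))
  cat(sprintf("  missing/gap cells: %.1f%%\n",
              100 * mean(x$tag %in% c("missing", "gap"))))
  invisible(x)
}

#' Summary statistics of a character matrix
#'
#' @param matrix a [char_matrix()].
#' @return A list with taxon/character counts, percent missing (including
#'   gap) cells, percent polymorphic cells, and counts by character kind.
#' @examples
#' m <- matrix_from_states(rbind(A = c(0, 0), B = c(0, 1), C = c(1, 1),
#'                               D = c(1, NA)))
#' matrix_summary(m)$pct_missing
#' @export
matrix_summary <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  list(
    n_taxa = length(matrix$taxa),
    n_characters = ncol(matrix$cells),
    pct_missing = 100 * mean(matrix$tag %in% c("missing", "gap")),
    pct_uncertain = 100 * mean(matrix$tag == "uncertain"),
    n_ordered = sum(matrix$ordered),
    n_unordered = sum(!matrix$ordered),
    n_active_taxa = sum(matrix$active_taxa),
    n_active_characters = sum(matrix$active_chars)
  )
}

# Pack the active part of a matrix for the C++ scorer, with rows in the
# order of `taxa` (default: all taxa of the matrix).
.pack_matrix <- function(cm, taxa = cm$taxa, chars = which(cm$active_chars)) {
  rows <- match(taxa, cm$taxa)
  if (anyNA(rows)) stop("unknown taxa: ", paste(taxa[is.na(rows)], collapse = ", "))
  list(
    mask = cm$cells[rows, chars, drop = FALSE],
    nstates = cm$nstates[chars],
    ordered = cm$ordered[chars],
    weights = cm$weights[chars],
    chars = chars,
    taxa = taxa
  )
}
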