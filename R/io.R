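#' Read a discrete character matrix (NEXUS or TNT)
#'
#' Parses the two matrix dialects used for morphological parsimony work:
#' NEXUS `DATA`/`CHARACTERS` blocks (with an optional `ASSUMPTIONS` block
#' carrying a `TYPESET` of ordered characters) and TNT `xread` (with an
#' optional `ccode` block).  `?` maps to missing (the full state alphabet),
#' `-` to gap, which is scored identically to missing; parenthesized or
#' braced groups (`(01)`, `{01}`, and `[01]` in TNT) map to uncertain
#' multi-state cells.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"nexus"`, `"tnt"`, or `"auto"` (detect from content).
#' @return A [char_matrix()].
#' @examples
#' nex <- c("#NEXUS", "BEGIN DATA;",
#'          "DIMENSIONS NTAX=2 NCHAR=2;",
#'          "FORMAT MISSING=? GAP=-;",
#'          "MATRIX", "A 01", "B 10", ";", "END;")
#' m <- read_matrix(nex)
#' matrix_summary(m)$n_taxa
#' @export
read_matrix <- function(source, dialect = c("auto", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE))) "nexus"
    else if (any(grepl("\\bxread\\b", lines, ignore.case = TRUE))) "tnt"
    else stop("cannot auto-detect matrix dialect (no #NEXUS header or xread)")
  }
  if (dialect == "nexus") .read_nexus(lines) else .read_tnt(lines)
}

# tokenizes one matrix row body into per-cell bitmasks + tags
.parse_cells <- function(body, nstates_hint, symbols, lineno,
                         open = "({", close = ")}", missing_ch = "?",
                         gap_ch = "-") {
  chars <- strsplit(body, "")[[1]]
  chars <- chars[chars != " " & chars != "\t"]
  cells <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% strsplit(open, "")[[1]]) {
      cl <- strsplit(close, "")[[1]][match(ch, strsplit(open, "")[[1]])]
      j <- i + 1
      grp <- character(0)
      while (j <= length(chars) && chars[j] != cl) {
        grp <- c(grp, chars[j])
        j <- j + 1
      }
      if (j > length(chars))
        stop(sprintf("line %d: unterminated state group", lineno))
      st <- match(grp, symbols) - 1L
      if (anyNA(st))
        stop(sprintf("line %d: unknown state symbol '%s'",
                     lineno, paste(grp[is.na(st)], collapse = "")))
      cells[[length(cells) + 1L]] <- list(states = st, tag = "uncertain")
      i <- j + 1
    } else if (ch == missing_ch) {
      cells[[length(cells) + 1L]] <- list(states = NULL, tag = "missing")
      i <- i + 1
    } else if (ch == gap_ch) {
      cells[[length(cells) + 1L]] <- list(states = NULL, tag = "gap")
      i <- i + 1
    } else {
      st <- match(ch, symbols) - 1L
      if (is.na(st))
        stop(sprintf("line %d: unknown state symbol '%s'", lineno, ch))
      cells[[length(cells) + 1L]] <- list(states = st, tag = "observed")
      i <- i + 1
    }
  }
  cells
}

.assemble_matrix <- function(rows, taxa, ntax, nchar, ordered_idx, symbols,
                             weights = NULL, inactive_idx = integer(0)) {
  if (length(taxa) != ntax)
    stop(sprintf("dimension mismatch: %d taxon rows found, NTAX=%d declared%s",
                 length(taxa), ntax,
                 if (length(taxa)) paste0(" (last row: ", tail(taxa, 1), ")") else ""))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != nchar)
      stop(sprintf("dimension mismatch for taxon '%s': %d cells, NCHAR=%d declared",
                   taxa[i], length(rows[[i]]), nchar))
  }
  # alphabet per character: highest state mentioned + 1
  nstates <- vapply(seq_len(nchar), function(j) {
    mx <- -1L
    for (i in seq_len(ntax)) {
      s <- rows[[i]][[j]]$states
      if (length(s)) mx <- max(mx, max(s))
    }
    max(mx + 1L, 1L)
  }, integer(1))
  cells <- matrix(0L, ntax, nchar)
  tag <- matrix("observed", ntax, nchar)
  for (i in seq_len(ntax)) {
    for (j in seq_len(nchar)) {
      cl <- rows[[i]][[j]]
      tag[i, j] <- cl$tag
      cells[i, j] <- if (is.null(cl$states)) .full_mask(nstates[j])
                     else .bitmask(cl$states)
    }
  }
  ordered <- rep(FALSE, nchar)
  ordered[ordered_idx] <- TRUE
  active <- rep(TRUE, nchar)
  active[inactive_idx] <- FALSE
  w <- rep(1, nchar)
  if (!is.null(weights)) w[seq_along(weights)] <- weights
  char_matrix(cells, taxa = taxa, tag = tag, ordered = ordered,
              nstates = nstates, weights = w, active_chars = active,
              symbols = symbols)
}

.strip_nexus_comments <- function(lines) gsub("\\[[^]]*\\]", "", lines)

.read_nexus <- function(lines) {
  raw <- lines
  lines <- .strip_nexus_comments(lines)
  up <- toupper(lines)
  dim_line <- grep("DIMENSIONS", up)
  if (!length(dim_line)) stop("no DIMENSIONS statement found")
  dl <- paste(lines[dim_line[1]:length(lines)], collapse = " ")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dl, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dl, ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_)) stop("could not parse NTAX/NCHAR")
  symbols <- .parsikit_symbols
  fmt_line <- grep("FORMAT", up)
  missing_ch <- "?"; gap_ch <- "-"
  if (length(fmt_line)) {
    fl <- lines[fmt_line[1]]
    if (grepl("MISSING\\s*=\\s*\\S", fl, ignore.case = TRUE))
      missing_ch <- sub(".*MISSING\\s*=\\s*(\\S).*", "\\1", fl, ignore.case = TRUE)
    if (grepl("GAP\\s*=\\s*\\S", fl, ignore.case = TRUE))
      gap_ch <- sub(".*GAP\\s*=\\s*(\\S).*", "\\1", fl, ignore.case = TRUE)
  }
  mat_start <- grep("^\\s*MATRIX\\s*$", up)
  if (!length(mat_start)) mat_start <- grep("\\bMATRIX\\b", up)
  if (!length(mat_start)) stop("no MATRIX statement found")
  i <- mat_start[1] + 1
  taxa <- character(0)
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^;", ln) || grepl(";\\s*$", ln) && ln == ";") break
    if (ln == ";") break
    if (nzchar(ln)) {
      ln2 <- sub(";\\s*$", "", ln)
      m <- regmatches(ln2, regexec("^('([^']+)'|\\\"([^\\\"]+)\\\"|\\S+)\\s+(.*)$", ln2))[[1]]
      if (length(m)) {
        name <- if (nzchar(m[3])) m[3] else if (nzchar(m[4])) m[4] else m[2]
        body <- m[5]
        cellrow <- .parse_cells(body, NULL, symbols, i,
                                missing_ch = missing_ch, gap_ch = gap_ch)
        k <- match(name, taxa)
        if (is.na(k)) {          # new taxon
          taxa <- c(taxa, name)
          rows[[length(rows) + 1L]] <- cellrow
        } else {                  # interleaved continuation
          rows[[k]] <- c(rows[[k]], cellrow)
        }
      }
      if (grepl(";\\s*$", ln)) break
    }
    i <- i + 1
  }
  ordered_idx <- .parse_nexus_typeset(lines, nchar_)
  .assemble_matrix(rows, taxa, ntax, nchar_, ordered_idx, symbols)
}

.expand_ranges <- function(txt, sep = "-") {
  # "1 3-5 8" -> c(1,3,4,5,8)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  out <- integer(0)
  for (t in toks) {
    if (grepl(sep, t, fixed = TRUE)) {
      ab <- as.integer(strsplit(t, sep, fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(t))
  }
  out
}

.parse_nexus_typeset <- function(lines, nchar_) {
  up <- toupper(lines)
  ts <- grep("TYPESET", up)
  if (!length(ts)) return(integer(0))
  # gather statement until ';'
  stmt <- character(0)
  i <- ts[1]
  repeat {
    stmt <- c(stmt, lines[i])
    if (grepl(";", lines[i]) || i >= length(lines)) break
    i <- i + 1
  }
  stmt <- paste(stmt, collapse = " ")
  stmt <- sub(";.*$", "", stmt)
  stmt <- sub(".*=", "", stmt)
  ordered_idx <- integer(0)
  parts <- strsplit(stmt, ",")[[1]]
  for (p in parts) {
    kv <- strsplit(p, ":")[[1]]
    if (length(kv) != 2) next
    kind <- trimws(tolower(kv[1]))
    idx <- .expand_ranges(kv[2])
    if (kind %in% c("ord", "ordered", "wagner")) ordered_idx <- c(ordered_idx, idx)
  }
  ordered_idx[ordered_idx >= 1 & ordered_idx <= nchar_]
}

.read_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # drop quoted title after xread
  m <- regexec("xread\\s*(?:'[^']*'\\s*)?(\\d+)\\s+(\\d+)(.*)", txt)[[1]]
  mm <- regmatches(txt, regexec("xread\\s*(?:'[^']*'\\s*)?(\\d+)\\s+(\\d+)", txt))[[1]]
  if (!length(mm)) stop("no xread statement found")
  nchar_ <- as.integer(mm[2])
  ntax <- as.integer(mm[3])
  body_start <- regexpr(mm[1], txt, fixed = TRUE) + nchar(mm[1])
  rest <- substr(txt, body_start, nchar(txt))
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0) stop("xread block not terminated by ';'")
  body <- substr(rest, 1, semi - 1)
  body_lines <- strsplit(body, "\n")[[1]]
  taxa <- character(0)
  rows <- list()
  for (li in seq_along(body_lines)) {
    ln <- trimws(body_lines[li])
    if (!nzchar(ln)) next
    m2 <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1]]
    if (!length(m2)) next
    name <- m2[2]
    cellrow <- .parse_cells(m2[3], NULL, .parsikit_symbols, li,
                            open = "[", close = "]")
    k <- match(name, taxa)
    if (is.na(k)) {
      taxa <- c(taxa, name)
      rows[[length(rows) + 1L]] <- cellrow
    } else {
      rows[[k]] <- c(rows[[k]], cellrow)
    }
  }
  cc <- .parse_tnt_ccode(txt, nchar_)
  .assemble_matrix(rows, taxa, ntax, nchar_, cc$ordered, .parsikit_symbols,
                   inactive_idx = cc$inactive)
}

# ccode uses 0-based character indices and N.M ranges; '+' marks ordered
# (additive), '-' unordered, '[' active, ']' inactive.
.parse_tnt_ccode <- function(txt, nchar_) {
  out <- list(ordered = integer(0), inactive = integer(0))
  m <- regmatches(txt, regexec("ccode([^;]*);", txt))[[1]]
  if (!length(m)) return(out)
  toks <- strsplit(trimws(m[2]), "\\s+")[[1]]
  mode <- NULL
  idx_of <- function(t) {
    if (grepl(".", t, fixed = TRUE)) {
      ab <- as.integer(strsplit(t, ".", fixed = TRUE)[[1]])
      seq(ab[1], ab[2]) + 1L
    } else as.integer(t) + 1L
  }
  for (t in toks) {
    if (!nzchar(t)) next
    first <- substr(t, 1, 1)
    if (first %in% c("+", "-", "[", "]", "/", "*")) {
      mode <- first
      t <- substr(t, 2, nchar(t))
      if (first == "/") t <- sub("^\\d+", "", t)  # weight value: ignored
      if (!nzchar(t)) next
    }
    if (is.null(mode) || !grepl("^\\d", t)) next
    idx <- idx_of(t)
    idx <- idx[idx >= 1 & idx <= nchar_]
    if (mode == "+") out$ordered <- union(out$ordered, idx)
    if (mode == "-") out$ordered <- setdiff(out$ordered, idx)
    if (mode == "]") out$inactive <- union(out$inactive, idx)
    if (mode == "[") out$inactive <- setdiff(out$inactive, idx)
  }
  out
}

#' Write a character matrix to NEXUS or TNT text
#'
#' The output round-trips: `read_matrix(write_matrix(m))` reproduces every
#' cell, tag, and ordering flag.  Ordered characters are emitted in an
#' ASSUMPTIONS `TYPESET` (NEXUS) or a `ccode` block (TNT).
#'
#' @param matrix a [char_matrix()].
#' @param dialect `"nexus"` or `"tnt"`.
#' @param path optional file to write to.
#' @return The text, invisibly when `path` is given.
#' @export
write_matrix <- function(matrix, dialect = c("nexus", "tnt"), path = NULL) {
  stopifnot(inherits(matrix, "char_matrix"))
  dialect <- match.arg(dialect)
  if (ncol(matrix$cells) < 1) stop("refusing to write a matrix with no characters")
  sym <- matrix$symbols
  cell_txt <- function(i, j, open = "(", close = ")") {
    tg <- matrix$tag[i, j]
    if (tg == "missing") return("?")
    if (tg == "gap") return("-")
    st <- .mask_states(matrix$cells[i, j])
    if (length(st) == 1) sym[st + 1] else
      paste0(open, paste(sym[st + 1], collapse = ""), close)
  }
  nt <- length(matrix$taxa); nc <- ncol(matrix$cells)
  name_pad <- formatC(gsub(" ", "_", matrix$taxa),
                      width = max(nchar(matrix$taxa)) + 2, flag = "-")
  if (dialect == "nexus") {
    rows <- vapply(seq_len(nt), function(i) {
      paste0(name_pad[i],
             paste(vapply(seq_len(nc), function(j) cell_txt(i, j), ""),
                   collapse = ""))
    }, "")
    out <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
             "FORMAT MISSING=? GAP=- SYMBOLS=\"0 1 2 3 4 5 6 7 8 9\";",
             "MATRIX", rows, ";", "END;")
    if (any(matrix$ordered)) {
      out <- c(out, "", "BEGIN ASSUMPTIONS;",
               sprintf("TYPESET * default = ord: %s;",
                       paste(which(matrix$ordered), collapse = " ")),
               "END;")
    }
  } else {
    rows <- vapply(seq_len(nt), function(i) {
      paste0(name_pad[i],
             paste(vapply(seq_len(nc), function(j) cell_txt(i, j, "[", "]"), ""),
                   collapse = ""))
    }, "")
    out <- c(sprintf("xread %d %d", nc, nt), rows, ";")
    if (any(matrix$ordered) || any(!matrix$active_chars)) {
      cc <- "ccode"
      if (any(matrix$ordered))
        cc <- paste(cc, "+", paste(which(matrix$ordered) - 1L, collapse = " "))
      if (any(!matrix$active_chars))
        cc <- paste(cc, "]", paste(which(!matrix$active_chars) - 1L, collapse = " "))
      out <- c(out, paste0(cc, ";"))
    }
    out <- c(out, "proc /;")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
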