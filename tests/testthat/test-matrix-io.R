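test_that("NEXUS parsing maps tokens to the documented state sets", {
  nex <- c("#NEXUS", "BEGIN DATA;",
           "DIMENSIONS NTAX=3 NCHAR=4;",
           "FORMAT MISSING=? GAP=-;",
           "MATRIX",
           "A 01?2",
           "B 10(01)0",
           "C 1-{12}1",
           ";", "END;")
  m <- read_matrix(nex, dialect = "nexus")
  expect_equal(length(m$taxa), 3)
  expect_equal(ncol(m$cells), 4)
  # singleton observed cells
  expect_equal(parsikit:::.mask_states(m$cells["A" == m$taxa, 1][[1]]), 0L)
  expect_equal(m$tag[1, 1], "observed")
  # '?' in a 3-state character covers the full alphabet
  expect_equal(m$nstates[3], 3L)
  expect_equal(sort(parsikit:::.mask_states(m$cells[1, 3])), 0:2)
  expect_equal(m$tag[1, 3], "missing")
  # parenthesized and braced groups are uncertain state sets
  expect_equal(sort(parsikit:::.mask_states(m$cells[2, 3])), 0:1)
  expect_equal(m$tag[2, 3], "uncertain")
  expect_equal(sort(parsikit:::.mask_states(m$cells[3, 3])), 1:2)
  # gap is recorded as gap but carries the full alphabet (scored as missing)
  expect_equal(m$tag[3, 2], "gap")
  expect_equal(sort(parsikit:::.mask_states(m$cells[3, 2])), 0:1)
})

test_that("two-taxon two-character body transcribes directly", {
  nex <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
           "FORMAT MISSING=? GAP=-;", "MATRIX", "A 01", "B 10", ";", "END;")
  m <- read_matrix(nex)
  expect_equal(m$taxa, c("A", "B"))
  expect_true(all(m$tag == "observed"))
  expect_equal(unname(m$cells[, 1]), c(1L, 2L))  # states 0,1 as bitmasks
})

test_that("parse errors name the offender", {
  bad_dim <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=2;",
               "MATRIX", "A 01", "B 10", ";", "END;")
  expect_error(read_matrix(bad_dim), "dimension mismatch")
  bad_row <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
               "MATRIX", "A 01", "B 100", ";", "END;")
  expect_error(read_matrix(bad_row), "taxon 'B'")
  bad_sym <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
               "MATRIX", "A 01", "B 1!", ";", "END;")
  expect_error(read_matrix(bad_sym), "line \\d+.*unknown state symbol")
})

test_that("TNT xread with ccode reads dimensions, ordering and activity", {
  tnt <- c("xread 'a comment' 4 3",
           "tax1 0101",
           "tax2 1[01]01",
           "tax3 ?201",
           ";",
           "ccode + 1 - 0 ] 3;",
           "proc /;")
  m <- read_matrix(tnt)
  expect_equal(length(m$taxa), 3)
  expect_equal(ncol(m$cells), 4)
  expect_equal(m$ordered, c(FALSE, TRUE, FALSE, FALSE))  # 0-based ccode
  expect_equal(m$active_chars, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(m$tag[2, 2], "uncertain")
  expect_equal(m$tag[3, 1], "missing")
})

test_that("write/read round-trips cells, tags, and character kinds", {
  set.seed(11)
  for (dialect in c("nexus", "tnt")) {
    for (rep in 1:5) {
      m <- random_matrix(n_taxa = sample(4:8, 1), n_chars = sample(3:10, 1),
                         max_states = 4, p_missing = 0.2, p_ordered = 0.3)
      # sprinkle uncertain cells
      j <- sample(ncol(m$cells), 1)
      i <- sample(nrow(m$cells), 1)
      if (m$nstates[j] >= 2) {
        m$cells[i, j] <- parsikit:::.bitmask(c(0L, 1L))
        m$tag[i, j] <- "uncertain"
      }
      m2 <- read_matrix(write_matrix(m, dialect), dialect = dialect)
      expect_equal(unname(m2$cells), unname(m$cells))
      expect_equal(unname(m2$tag), unname(m$tag))
      expect_equal(m2$ordered, m$ordered)
      expect_equal(m2$taxa, m$taxa)
    }
  }
})

test_that("parsing is order-preserving", {
  nex <- c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=3;",
           "MATRIX", "Z 012", "A 120", "M 201", ";", "END;")
  m <- read_matrix(nex)
  expect_equal(m$taxa, c("Z", "A", "M"))
  expect_equal(parsikit:::.mask_states(m$cells[2, 3]), 0L)
})

test_that("writing an empty character set is refused", {
  m <- fixture_f1()
  m$cells <- m$cells[, 0, drop = FALSE]
  expect_error(write_matrix(m), "no characters")
})

test_that("matrix_summary reports consistent percentages", {
  m <- fixture_f1()
  expect_equal(matrix_summary(m)$pct_missing, 0)
  states <- rbind(A = c(0, 0, 0), B = c(0, 1, 1), C = c(1, 0, 1),
                  D = c(1, 1, NA))
  m2 <- matrix_from_states(states)
  expect_equal(matrix_summary(m2)$pct_missing, 100 / 12, tolerance = 1e-4)
  s <- matrix_summary(m2)
  expect_equal(s$n_taxa, 4)
  expect_equal(s$n_ordered + s$n_unordered, s$n_characters)
})
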