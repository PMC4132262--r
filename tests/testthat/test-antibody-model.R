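test_that("mutation notation parses and rejects malformed strings", {
  m <- parse_mutation("HC:G54I")
  expect_equal(m$chain, "HC")
  expect_equal(m$position, 54L)
  expect_equal(m$wt_aa, "G")
  expect_equal(m$mut_aa, "I")

  m2 <- parse_mutation("LC: E1S")
  expect_equal(m2$chain, "LC")
  expect_equal(m2$position, 1L)
  expect_equal(m2$wt_aa, "E")
  expect_equal(m2$mut_aa, "S")

  expect_error(parse_mutation("LC:A5A"), "identity")
  expect_error(parse_mutation("XC:A5G"), "malformed")
  expect_error(parse_mutation("HC:G54"), "malformed")
  expect_error(parse_mutation("HC:B54I"), "non-standard")
  expect_error(parse_mutation("HC:G0I"), "position|malformed")
  # identity allowed when flagged (scanner self-tests)
  expect_silent(parse_mutation("LC:A5A", allow_identity = TRUE))
})

test_that("apply_mutations substitutes exactly the mutated positions", {
  s <- v_region("QVQLVESGGG", "heavy", name = "toy")
  out <- apply_mutations(s, parse_mutation("HC:Q1E"))
  expect_equal(as.character(out), "EVQLVESGGG")
  expect_equal(out$region_map, s$region_map)

  expect_equal(as.character(apply_mutations(s, list())), as.character(s))

  expect_error(apply_mutations(s, list(parse_mutation("HC:Q1E"),
                                       parse_mutation("HC:Q1K"))),
               "duplicate")
  expect_error(apply_mutations(s, parse_mutation("HC:A2G")),
               "expected A, found V")
  expect_error(apply_mutations(s, parse_mutation("LC:Q1E")), "light")
})

test_that("diff_sequences inverts apply_mutations on 1000 seeded cases", {
  set.seed(42)
  s <- random_vregion(60)
  expect_length(diff_sequences(s, s), 0)
  short <- random_vregion(59)
  expect_error(diff_sequences(s, short), "length mismatch")

  chain <- "HC"
  for (i in 1:1000) {
    k <- sample(0:6, 1)
    pos <- sort(sample(60, k))
    muts <- lapply(pos, function(p) {
      wt <- s$residues[p]
      point_mutation(chain, p, wt, sample(setdiff(LETTERS[LETTERS %in% c(
        "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
        "Q", "R", "S", "T", "V", "W", "Y")], wt), 1))
    })
    b <- apply_mutations(s, muts)
    got <- diff_sequences(s, b)
    expect_equal(vapply(got, format, character(1)),
                 vapply(muts, format, character(1)))
    expect_equal(as.character(apply_mutations(s, got)), as.character(b))
  }
})

test_that("v_region validates residues and canonical region order", {
  expect_error(v_region("ABZ", "heavy"), "non-standard")
  expect_error(v_region("", "heavy"), "empty")
  rmap <- c(rep("FR1", 2), rep("CDR1", 2), rep("FR2", 2))
  expect_silent(v_region("AAAAAA", "heavy", region_map = rmap))
  expect_error(v_region("AAAAAA", "heavy",
                        region_map = c(rep("CDR1", 3), rep("FR1", 3))),
               "canonical order")
  expect_error(v_region("AAAA", "heavy", region_map = rep("FR1", 3)),
               "length")
})

test_that("FASTA round trip preserves names, chain kinds and sequences", {
  seqs <- list(v_region("QVQLVESGGG", "heavy", name = "hv1"),
               v_region("EIVMTQ", "light", name = "lv1"))
  f <- tempfile(fileext = ".fasta")
  write_vregion_fasta(seqs, f)
  back <- read_vregion_fasta(f)
  expect_equal(names(back), c("hv1", "lv1"))
  expect_equal(back$hv1$chain_kind, "heavy")
  expect_equal(back$lv1$chain_kind, "light")
  expect_equal(as.character(back$hv1), "QVQLVESGGG")
})

test_that("PDB reading matches an independent ATOM-record line count", {
  s <- toy_fab_cached()
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  n_lines <- sum(startsWith(readLines(f), "ATOM"))
  r <- read_pdb(f)
  expect_equal(nrow(r$atoms), n_lines)
  expect_equal(sort(unique(r$atoms$chain)), c("H", "L"))
  expect_equal(nrow(r$atoms), nrow(s$atoms))
})

test_that("PDB write/read is idempotent at the format's precision", {
  s <- toy_fab_cached()
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(s, f1)
  r1 <- read_pdb(f1)
  write_pdb(r1, f2)
  r2 <- read_pdb(f2)
  expect_equal(as.matrix(r1$atoms[, c("x", "y", "z")]),
               as.matrix(r2$atoms[, c("x", "y", "z")]), tolerance = 1e-9)
  # and the first read agrees with the source to 3 decimals (PDB precision)
  expect_lt(max(abs(as.matrix(r1$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 5.1e-4)
})

test_that("degenerate PDB inputs are handled", {
  f <- tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "no ATOM records")

  # one alanine with complete backbone parses to 1 chain / 1 residue
  ala <- build_extended_peptide("A")
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(ala, f2)
  r <- read_pdb(f2)
  expect_equal(length(unique(r$atoms$chain)), 1L)
  expect_equal(length(unique(r$atoms$resno)), 1L)
  expect_equal(sort(r$atoms$elety), sort(c("N", "CA", "C", "O", "CB")))

  # missing backbone atom -> warning, residue flagged
  a <- ala$atoms[ala$atoms$elety != "O", ]
  expect_warning(inc <- fab_structure(a), "incomplete backbone")
  expect_false(any(inc$atoms$complete_bb))
})

test_that("altloc records resolve to highest occupancy", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.300   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       3.100   1.500   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  r <- read_pdb(f)
  n_atom <- r$atoms[r$atoms$elety == "N", ]
  expect_equal(nrow(n_atom), 1L)
  expect_equal(n_atom$x, 1.0)
})
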