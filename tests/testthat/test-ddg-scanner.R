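test_that("pair at the Lennard-Jones minimum contributes exactly -epsilon", {
  # two carbon atoms in different residues at r = rmin_i + rmin_j (3.8 A),
  # no charges: closed-form LJ minimum
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  nb <- abrefine:::.nonbonded_cpp(xyz, eps = c(0.1, 0.1), rmin = c(1.9, 1.9),
                                  q = c(0, 0), res = c(1L, 2L),
                                  chain = c(1L, 1L), bbcb = c(0L, 0L),
                                  r_on = 6, r_off = 8, kdiel = 4)
  expect_equal(nb$vdw, -0.1, tolerance = 1e-12)
  expect_equal(nb$elec, 0)

  # same-residue pair is excluded entirely
  nb2 <- abrefine:::.nonbonded_cpp(xyz, c(0.1, 0.1), c(1.9, 1.9), c(1, -1),
                                   res = c(1L, 1L), chain = c(1L, 1L),
                                   bbcb = c(0L, 0L), 6, 8, 4)
  expect_equal(nb2$vdw, 0)
  expect_equal(nb2$elec, 0)
})

test_that("an isolated alanine has zero vdW and identical repeat breakdowns", {
  ala <- build_extended_peptide("A")
  e1 <- fold_energy(ala)
  expect_equal(e1$vdw, 0)
  e2 <- fold_energy(ala)
  expect_identical(unlist(e1), unlist(e2))  # bitwise-stable
})

test_that("weighted total is the dot product of terms and weights", {
  e <- toy_fab_energy_cached()
  terms <- c(e$vdw, e$electrostatic_coulomb, e$polar_solvation_gb,
             e$nonpolar_sasa, e$sidechain_entropy)
  expect_equal(e$weighted_total, sum(terms), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:3) {
    wv <- stats::runif(5, -2, 2)
    w <- term_weights(wv[1], wv[2], wv[3], wv[4], wv[5])
    ew <- fold_energy(toy_fab_cached(), w)
    expect_equal(ew$weighted_total, sum(terms * wv), tolerance = 1e-9)
  }
})

test_that("identity mutations have exactly zero ddG", {
  s <- toy_fab_cached()
  ef <- toy_fab_energy_cached()
  seqH <- fab_chain_sequence(s, "H")
  for (p in c(1, 7, 13, 30, 45, 60)) {
    m <- point_mutation("HC", p, seqH[p], seqH[p], allow_identity = TRUE)
    r <- mutation_energy(s, m, folded_wt = ef)
    expect_identical(r$ddg, 0)
  }
})

test_that("mutation to glycine removes all side-chain atoms", {
  s <- toy_fab_cached()
  seqH <- fab_chain_sequence(s, "H")
  p <- which(seqH == "A")[1]
  mut <- build_mutant_structure(s, point_mutation("HC", p, "A", "G"))
  rows <- mut$atoms[mut$atoms$chain == "H" & mut$atoms$resno == p, ]
  expect_equal(sort(rows$elety), sort(c("N", "CA", "C", "O")))
  expect_equal(unique(rows$resid), "GLY")
  # backbone coordinates untouched
  old <- s$atoms[s$atoms$chain == "H" & s$atoms$resno == p &
                   s$atoms$elety %in% c("N", "CA", "C", "O"), ]
  expect_equal(as.matrix(rows[match(old$elety, rows$elety), c("x", "y", "z")]),
               as.matrix(old[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("chosen rotamer minimizes the clash count over the full library", {
  s <- toy_fab_cached()
  buried <- attr(s, "buried_sites")
  site <- buried[buried$resid != "GLY", ][1, ]
  wt <- abrefine:::aa_one(site$resid)
  m <- point_mutation(if (site$chain == "H") "HC" else "LC", site$resno,
                      wt, "F")
  mut <- build_mutant_structure(s, m)
  # exhaustive enumeration over the rotamer table
  rows <- abrefine:::residue_rows(s, site$chain, site$resno)
  bb <- abrefine:::residue_backbone(s, rows)
  env <- abrefine:::clash_environment(s, site$chain, site$resno)
  rots <- abrefine:::rotamer_set("PHE")
  clashes <- vapply(seq_len(nrow(rots)), function(k) {
    sc <- abrefine:::build_sidechain(
      "PHE", bb, as.numeric(rots[k, c("chi1", "chi2", "chi3", "chi4")]))
    abrefine:::count_clashes(do.call(rbind, sc), names(sc), env)
  }, numeric(1))
  pick <- abrefine:::place_best_rotamer("PHE", bb, env)
  expect_equal(pick$clashes, min(clashes))
  expect_equal(pick$rot, which.min(clashes))  # lowest index on ties
})

test_that("ddG is approximately involutive and exactly linear in weights", {
  s <- toy_fab_cached()
  ef <- toy_fab_energy_cached()
  exposed <- attr(s, "exposed_sites")
  site <- exposed[exposed$chain == "H" & exposed$resid == "SER", ][1, ]
  wt <- abrefine:::aa_one(site$resid)
  fwd <- point_mutation("HC", site$resno, wt, "F")
  r1 <- mutation_energy(s, fwd, folded_wt = ef)
  rev <- point_mutation("HC", site$resno, "F", wt)
  r2 <- mutation_energy(r1$mutant, rev)
  expect_lt(abs(r1$ddg + r2$ddg), 0.5)

  # doubling all weights doubles the weighted ddG exactly
  w2 <- term_weights(2, 2, 2, 2, 2)
  r1b <- mutation_energy(s, fwd, w = w2,
                         folded_wt = fold_energy(s, w2))
  expect_equal(r1b$ddg, 2 * r1$ddg, tolerance = 1e-9)
})

test_that("spatially distant mutations are energetically additive", {
  s <- toy_fab_cached()
  ef <- toy_fab_energy_cached()
  a <- s$atoms
  seqH <- fab_chain_sequence(s, "H")
  seqL <- fab_chain_sequence(s, "L")
  # verify the pair is > 12 A apart (minimum heavy-atom distance)
  x1 <- as.matrix(a[a$chain == "H" & a$resno == 5, c("x", "y", "z")])
  x2 <- as.matrix(a[a$chain == "L" & a$resno == 50, c("x", "y", "z")])
  dmin <- min(sqrt(outer(rowSums(x1^2), rowSums(x2^2), "+") -
                     2 * x1 %*% t(x2)))
  expect_gt(dmin, 12)
  m1 <- point_mutation("HC", 5, seqH[5], "F")
  m2 <- point_mutation("LC", 50, seqL[50], "K")
  r1 <- mutation_energy(s, m1, folded_wt = ef)
  r2 <- mutation_energy(s, m2, folded_wt = ef)
  r12 <- mutation_energy(s, list(m1, m2), folded_wt = ef)
  expect_lt(abs(r12$ddg - r1$ddg - r2$ddg), 0.1)
})

test_that("scan_mutations agrees with per-candidate calls and collects failures", {
  s <- toy_fab_cached()
  s2 <- toy_fab_cached(2)
  expect_length(scan_mutations(s, s2, list())$records, 0)

  seqH <- fab_chain_sequence(s, "H")
  set.seed(11)
  pos <- sample(which(seqH == fab_chain_sequence(s2, "H") & seqH != "G"), 5)
  cands <- lapply(pos, function(p)
    point_mutation("HC", p, seqH[p],
                   sample(setdiff(c("A", "S", "V", "T", "K"), seqH[p]), 1)))
  res <- scan_mutations(s, s2, cands)
  expect_length(res$records, 5)
  expect_length(res$failures, 0)
  ef1 <- fold_energy(s); ef2 <- fold_energy(s2)
  for (i in seq_along(cands)) {
    expect_equal(res$records[[i]]$ddg_parental,
                 mutation_energy(s, cands[[i]], folded_wt = ef1)$ddg)
    expect_equal(res$records[[i]]$ddg_model,
                 mutation_energy(s2, cands[[i]], folded_wt = ef2)$ddg)
  }

  # wt mismatch on one candidate is reported, scan continues
  bad <- point_mutation("HC", pos[1], setdiff(c("W", "Y"), seqH[pos[1]])[1], "A")
  res2 <- scan_mutations(s, s2, c(cands[2], list(bad)))
  expect_length(res2$records, 1)
  expect_length(res2$failures, 1)
  expect_match(res2$failures[[1]], "mismatch")
})

test_that("identity scan over three identity candidates returns 0/0 records", {
  s <- toy_fab_cached()
  seqL <- fab_chain_sequence(s, "L")
  cands <- lapply(c(2, 10, 20), function(p)
    point_mutation("LC", p, seqL[p], seqL[p], allow_identity = TRUE))
  res <- scan_mutations(s, s, cands)
  for (r in res$records) {
    expect_identical(r$ddg_parental, 0)
    expect_identical(r$ddg_model, 0)
  }
})
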