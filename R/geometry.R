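# internal-coordinate geometry: NeRF atom placement, idealized backbones,
# side-chain construction from the coarse rotamer library, mutant building

DEG <- pi / 180

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
vnormalize <- function(v) v / sqrt(sum(v * v))

# place atom D bonded to C, with angle(B,C,D) and torsion(A,B,C,D)
place_atom <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * DEG
  ph <- dihedral_deg * DEG
  bc <- vnormalize(C - B)
  n <- vnormalize(vcross(B - A, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vnormalize(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
}

# idealized backbone internal coordinates
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.7,
                a_ca_c_o = 120.5, t_cb = 122.5, a_n_ca_cb = 110.5, b_ca_cb = 1.53)

# reconstruct CB from backbone (used for glycine targets and seed building)
reconstruct_cb <- function(n, ca, c) {
  g <- BB_GEOM
  place_atom(c, n, ca, g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
}

# build an idealized backbone (N, CA, C, O per residue) from phi/psi lists;
# returns list of per-residue coordinate lists
build_backbone_coords <- function(n_res, phi, psi, omega = 180) {
  g <- BB_GEOM
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  res <- vector("list", n_res)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, g$ca_c, g$a_n_ca_c, 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      prev <- res[[i - 1]]
      N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$a_ca_c_n, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, g$n_ca, g$a_c_n_ca, omega[i - 1])
      C <- place_atom(prev$C, N, CA, g$ca_c, g$a_n_ca_c, phi[i])
    }
    O <- place_atom(N, CA, C, g$c_o, g$a_ca_c_o, psi[i] - 180)
    res[[i]] <- list(N = N, CA = CA, C = C, O = O)
  }
  res
}

# side-chain atoms (beyond CB) for a residue type at given chi angles.
# bb: named list/rows with N, CA, C (+ CB unless GLY/ALA target).
build_sidechain <- function(restype, bb, chis) {
  top <- param_table("sidechain_topology")
  rows <- top[top$resid == restype, , drop = FALSE]
  coords <- list(N = bb$N, CA = bb$CA, C = bb$C)
  out <- list()
  if (restype == "GLY") return(out)
  cb <- bb$CB %||% reconstruct_cb(bb$N, bb$CA, bb$C)
  coords$CB <- cb
  out$CB <- cb
  if (!nrow(rows)) return(out)   # ALA
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    dih <- if (r$dref == "fix") r$doff else {
      ci <- as.integer(substr(r$dref, 4, 4))
      chis[ci] + r$doff
    }
    p <- place_atom(coords[[r$p3]], coords[[r$p2]], coords[[r$p1]],
                    r$b, r$ang, dih)
    coords[[r$atom]] <- p
    out[[r$atom]] <- p
  }
  out
}

rotamer_set <- function(restype) {
  rot <- param_table("rotamers")
  rot[rot$resid == restype, , drop = FALSE]
}

# steric clash count of candidate side-chain atoms against fixed atoms;
# clash = inter-atomic distance below 0.8 * sum of LJ radii.  Mirrors the
# energy function's exclusions: a candidate CB does not clash with
# backbone/CB atoms of sequence-adjacent residues.
count_clashes <- function(sc_xyz, sc_elety, env) {
  if (!nrow(sc_xyz) || !nrow(env$xyz)) return(0L)
  lj <- param_table("lj_params")
  ri <- lj$rmin[match(atom_element(sc_elety), lj$element)]
  n <- 0L
  for (i in seq_len(nrow(sc_xyz))) {
    keep <- if (sc_elety[i] == "CB") !env$adj_bbcb else TRUE
    d2 <- (env$xyz[keep, 1] - sc_xyz[i, 1])^2 +
      (env$xyz[keep, 2] - sc_xyz[i, 2])^2 +
      (env$xyz[keep, 3] - sc_xyz[i, 3])^2
    lim <- (0.8 * (ri[i] + env$rmin[keep]))^2
    n <- n + sum(d2 < lim)
  }
  n
}

# fixed-atom environment for clash tests around one residue: everything
# except the residue itself; adjacent backbone/CB atoms flagged so CB
# placement can ignore them (they are excluded pairs in the energy function)
clash_environment <- function(s, chain, resno, insert = "") {
  a <- s$atoms
  own <- a$chain == chain & a$resno == resno & a$insert == insert
  env <- a[!own, , drop = FALSE]
  lj <- param_table("lj_params")
  list(xyz = as.matrix(env[, c("x", "y", "z")]),
       rmin = lj$rmin[match(atom_element(env$elety), lj$element)],
       adj_bbcb = env$chain == chain & abs(env$resno - resno) == 1 &
         env$elety %in% c(BACKBONE_ATOMS, "CB"))
}

# choose the rotamer with fewest clashes (ties: lowest rotamer index) and
# return its side-chain atom list
place_best_rotamer <- function(restype, bb, env) {
  rots <- rotamer_set(restype)
  best <- NULL; best_n <- Inf
  for (k in seq_len(nrow(rots))) {
    chis <- as.numeric(rots[k, c("chi1", "chi2", "chi3", "chi4")])
    sc <- build_sidechain(restype, bb, chis)
    if (!length(sc)) return(list(atoms = sc, clashes = 0L, rot = 1L))
    xyz <- do.call(rbind, sc)
    ncl <- count_clashes(xyz, names(sc), env)
    if (ncl < best_n) {
      best_n <- ncl
      best <- list(atoms = sc, clashes = ncl, rot = k)
    }
  }
  best
}

residue_backbone <- function(s, rows) {
  a <- s$atoms[rows, ]
  g <- function(el) {
    i <- match(el, a$elety)
    if (is.na(i)) NULL else as.numeric(a[i, c("x", "y", "z")])
  }
  list(N = g("N"), CA = g("CA"), C = g("C"), O = g("O"), CB = g("CB"))
}

#' Build a point-mutant structure
#'
#' Backbone atoms (and the O) are left untouched; the side chain is replaced
#' by an idealized-geometry side chain grown along the existing CA-CB vector
#' (CB reconstructed from backbone geometry for glycine targets), with chi
#' angles from the coarse rotamer library and the rotamer chosen by lowest
#' clash count against the fixed neighbourhood (ties: lowest rotamer index).
#' No minimization is performed, so mutant building is fully deterministic.
#'
#' @param s a [fab_structure()].
#' @param m a [point_mutation()] (identity mutations allowed when flagged, in
#'   which case the structure is returned unchanged).
#' @param chain_map named character vector mapping `HC`/`LC` to PDB chain ids;
#'   never guessed.
#' @return mutated `fab_structure`.
#' @export
build_mutant_structure <- function(s, m, chain_map = c(HC = "H", LC = "L")) {
  stopifnot(inherits(s, "fab_structure"), inherits(m, "point_mutation"))
  ch <- chain_map[[m$chain]]
  if (is.null(ch)) stopf("chain_map lacks an entry for %s", m$chain)
  rows <- residue_rows(s, ch, m$position)
  if (!length(rows)) stopf("residue %s%d not found", ch, m$position)
  a <- s$atoms
  found <- aa_one(a$resid[rows[1]])
  if (found != m$wt_aa)
    stopf("wild-type mismatch at %s%d: expected %s, found %s",
          ch, m$position, m$wt_aa, found)
  if (!all(BACKBONE_ATOMS %in% a$elety[rows]))
    stopf("residue %s%d lacks a complete backbone", ch, m$position)
  if (m$identity) return(s)

  mut3 <- aa_three(m$mut_aa)
  bb <- residue_backbone(s, rows)
  env <- clash_environment(s, ch, m$position)
  pick <- place_best_rotamer(mut3, bb, env)

  keep_bb <- rows[a$elety[rows] %in% BACKBONE_ATOMS]
  sc <- pick$atoms
  new_rows <- if (length(sc)) {
    xyz <- do.call(rbind, sc)
    data.frame(chain = ch, resno = m$position, insert = "", resid = mut3,
               elety = names(sc), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, complete_bb = TRUE, stringsAsFactors = FALSE)
  } else NULL
  bb_rows <- a[keep_bb, , drop = FALSE]
  bb_rows$resid <- mut3
  before <- a[seq_len(min(rows) - 1), , drop = FALSE]
  after <- if (max(rows) < nrow(a)) a[(max(rows) + 1):nrow(a), , drop = FALSE] else NULL
  out <- s
  out$atoms <- rbind(before, bb_rows, new_rows, after)
  rownames(out$atoms) <- NULL
  out
}

#' Build an extended peptide with idealized geometry
#'
#' Idealized backbone at beta-strand torsions (default phi -139, psi 135)
#' with side chains packed by the minimum-clash rotamer rule.  This is the
#' scanner's unfolded-state reference (an isolated tripeptide centred on the
#' mutation site), exposed for testing and for constructing minimal inputs.
#'
#' @param seq1 character vector of one-letter residues.
#' @param phi,psi backbone torsions (degrees).
#' @return a [fab_structure()] with a single chain `"X"`.
#' @export
build_extended_peptide <- function(seq1, phi = -139, psi = 135) {
  res3 <- aa_three(seq1)
  n <- length(res3)
  bbs <- build_backbone_coords(n, phi, psi)
  rows <- list()
  for (i in seq_len(n)) {
    b <- bbs[[i]]
    rows[[i]] <- data.frame(chain = "X", resno = i, insert = "", resid = res3[i],
                            elety = BACKBONE_ATOMS,
                            x = c(b$N[1], b$CA[1], b$C[1], b$O[1]),
                            y = c(b$N[2], b$CA[2], b$C[2], b$O[2]),
                            z = c(b$N[3], b$CA[3], b$C[3], b$O[3]),
                            occ = 1, stringsAsFactors = FALSE)
  }
  s <- fab_structure(do.call(rbind, rows))
  # pack side chains residue by residue
  for (i in seq_len(n)) {
    if (res3[i] == "GLY") next
    rws <- residue_rows(s, "X", i)
    bb <- residue_backbone(s, rws)
    env <- clash_environment(s, "X", i)
    pick <- place_best_rotamer(res3[i], bb, env)
    sc <- pick$atoms
    if (!length(sc)) next
    xyz <- do.call(rbind, sc)
    add <- data.frame(chain = "X", resno = i, insert = "", resid = res3[i],
                      elety = names(sc), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], occ = 1, complete_bb = TRUE,
                      stringsAsFactors = FALSE)
    a <- s$atoms
    before <- a[seq_len(max(rws)), , drop = FALSE]
    after <- if (max(rws) < nrow(a)) a[(max(rws) + 1):nrow(a), , drop = FALSE] else NULL
    s$atoms <- rbind(before, add, after)
    rownames(s$atoms) <- NULL
  }
  s
}
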