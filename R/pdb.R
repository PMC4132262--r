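# Fab structures: atom-table container and PDB I/O (via bio3d)

#' Construct a Fab structure from an atom table
#'
#' The container is a single data frame of heavy atoms with one row per atom:
#' `chain`, `resno`, `insert`, `resid` (three-letter), `elety` (atom name),
#' `x`, `y`, `z`, `occ`.  Residues missing any backbone atom (N, CA, C, O)
#' are kept in the table but flagged and excluded from energetics.
#'
#' @param atoms data frame as above.
#' @return object of class `fab_structure` with attribute `incomplete`
#'   (data frame of residues failing the backbone check).
#' @export
fab_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stopf("atom table must have columns %s", paste(need, collapse = ", "))
  if (!nrow(atoms)) stopf("empty atom table")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  ord <- !duplicated(key)
  complete <- vapply(split(atoms$elety, factor(key, levels = key[ord])),
                     function(a) all(BACKBONE_ATOMS %in% a), logical(1))
  atoms$complete_bb <- complete[match(key, key[ord])]
  inc <- unique(atoms[!atoms$complete_bb,
                      c("chain", "resno", "insert", "resid")])
  if (nrow(inc))
    warning(sprintf("%d residue(s) with incomplete backbone excluded from energetics",
                    nrow(inc)), call. = FALSE)
  structure(list(atoms = atoms), class = "fab_structure",
            incomplete = inc)
}

#' @export
print.fab_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<fab_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno, a$insert))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

fab_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# unique residue table in file order
fab_residues <- function(s) {
  a <- s$atoms
  unique(a[, c("chain", "resno", "insert", "resid", "complete_bb")])
}

#' One-letter sequence of a structure chain (file order)
#' @param s a [fab_structure()].
#' @param chain chain id.
#' @return character vector of one-letter residues.
#' @export
fab_chain_sequence <- function(s, chain) {
  r <- fab_residues(s)
  r <- r[r$chain == chain, , drop = FALSE]
  if (!nrow(r)) stopf("no such chain: %s", chain)
  aa_one(r$resid)
}

# rows of one residue
residue_rows <- function(s, chain, resno, insert = "") {
  which(s$atoms$chain == chain & s$atoms$resno == resno &
          s$atoms$insert == insert)
}

#' Read a Fab structure from a PDB file
#'
#' Only ATOM records are honoured; HETATM and waters are ignored.  Alternate
#' locations are resolved to the highest occupancy (ties: first encountered);
#' insertion codes are preserved.  Hydrogens are dropped (the energy model is
#' united-atom).  Parsing is delegated to \pkg{bio3d}.
#'
#' @param file PDB path.
#' @return a [fab_structure()].
#' @export
read_pdb <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!any(startsWith(lines, "ATOM  "))) stopf("no ATOM records in %s", file)
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[is.na(a$elesy) | !trimws(a$elesy) %in% c("H", "D"), , drop = FALSE]
  a <- a[!startsWith(trimws(a$elety), "H"), , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc -> highest occupancy, ties first encountered
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- unlist(lapply(split(seq_len(nrow(a)), factor(key, levels = unique(key))),
                        function(i) i[which.max(a$o[i])]), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]
  fab_structure(data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                           resid = a$resid, elety = trimws(a$elety),
                           x = a$x, y = a$y, z = a$z, occ = a$o,
                           stringsAsFactors = FALSE))
}

#' Write a Fab structure to a PDB file
#'
#' Standard 80-column ATOM records via \pkg{bio3d}.
#'
#' @param s a `fab_structure`.
#' @param file output path.
#' @export
write_pdb <- function(s, file) {
  a <- s$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, insert = a$insert,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = a$occ, b = rep(0, nrow(a)))
  invisible(file)
}
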