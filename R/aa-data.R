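# amino-acid constants and bundled parameter tables

#' @keywords internal
"_PACKAGE"

#' @useDynLib abrefine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
names(AA3) <- AA1
AA1_FROM_3 <- stats::setNames(AA1, AA3)

aa_three <- function(one) {
  bad <- !one %in% AA1
  if (any(bad)) stopf("non-standard amino-acid letter: %s", one[bad][1])
  unname(AA3[one])
}

aa_one <- function(three) {
  bad <- !three %in% AA3
  if (any(bad)) stopf("non-standard residue name: %s", three[bad][1])
  unname(AA1_FROM_3[three])
}

# parameter-table cache, filled lazily from inst/extdata/params
.param_env <- new.env(parent = emptyenv())

param_table <- function(name) {
  if (!exists(name, envir = .param_env)) {
    f <- abr_file("params", paste0(name, ".csv"))
    assign(name, utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE),
           envir = .param_env)
  }
  get(name, envir = .param_env)
}

# element of a heavy atom from its PDB atom name (first letter for the
# standard protein set; no hydrogens are modelled)
atom_element <- function(elety) substr(elety, 1, 1)

# per-atom parameter lookup: LJ (eps, rmin), charge, GB radius
atom_params <- function(resid, elety) {
  el <- atom_element(elety)
  lj <- param_table("lj_params")
  gb <- param_table("gb_radii")
  i <- match(el, lj$element)
  if (anyNA(i)) stopf("no Lennard-Jones parameters for atom type: %s",
                      elety[is.na(i)][1])
  ch <- param_table("charges")
  q <- numeric(length(elety))
  bb <- match(paste("ALL", elety), paste(ch$resid, ch$atom))
  sc <- match(paste(resid, elety), paste(ch$resid, ch$atom))
  q[!is.na(bb)] <- ch$charge[bb[!is.na(bb)]]
  q[!is.na(sc)] <- ch$charge[sc[!is.na(sc)]]
  list(eps = lj$eps[i], rmin = lj$rmin[i], charge = q,
       rho = gb$rho[match(el, gb$element)])
}

# side-chain rotamer entropy term (kcal/mol, as -T*dS on folding)
residue_entropy <- function(resid) {
  tab <- param_table("rotamer_entropy")
  v <- tab$tds[match(resid, tab$resid)]
  v[is.na(v)] <- 0
  v
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
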