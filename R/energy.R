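# simplified folding-energy function and the point-mutation ddG scanner

#' Term weights for the weighted-sum mutation energy
#'
#' The scanner reports a weighted sum of van der Waals, Coulomb,
#' Generalized-Born polar solvation, nonpolar surface-area and side-chain
#' entropy terms.  All weights default to 1 and are dimensionless.
#'
#' @param vdw,elec,polar,nonpolar,entropy finite numeric weights.
#' @return object of class `term_weights`.
#' @export
term_weights <- function(vdw = 1, elec = 1, polar = 1, nonpolar = 1, entropy = 1) {
  w <- c(vdw = vdw, elec = elec, polar = polar, nonpolar = nonpolar,
         entropy = entropy)
  if (!all(is.finite(w))) stopf("term weights must be finite")
  structure(as.list(w), class = "term_weights")
}

#' Energy-function configuration
#'
#' Defaults: 8 A non-bonded cutoff with energy switching from 6 A,
#' distance-dependent dielectric eps(r) = 4r, surface tension
#' gamma = 0.0054 kcal/mol/A^2, Shrake-Rupley SASA with 960 fixed sphere
#' points and a 1.4 A probe, Still-style GB with coarse pairwise volume
#' descreening (scale 0.8) against intrinsic element radii.
#'
#' @param cutoff,switch_on non-bonded cutoff and switch-on distances (A).
#' @param diel_factor k in eps(r) = k*r.
#' @param gamma nonpolar surface tension (kcal/mol/A^2).
#' @param sasa_points,probe Shrake-Rupley sphere points and probe radius (A).
#' @param gb_descreen logical; use pairwise volume descreening for Born radii.
#' @param gb_descreen_scale,gb_alpha_max,gb_eps_w descreening scale, Born
#'   radius cap (A) and water dielectric.
#' @return list of class `energy_config`.
#' @export
energy_config <- function(cutoff = 8, switch_on = 6, diel_factor = 4,
                          gamma = 0.0054, sasa_points = 960, probe = 1.4,
                          gb_descreen = TRUE, gb_descreen_scale = 0.8,
                          gb_alpha_max = 25, gb_eps_w = 80) {
  structure(list(cutoff = cutoff, switch_on = switch_on,
                 diel_factor = diel_factor, gamma = gamma,
                 sasa_points = as.integer(sasa_points), probe = probe,
                 gb_descreen = gb_descreen,
                 gb_descreen_scale = gb_descreen_scale,
                 gb_alpha_max = gb_alpha_max, gb_eps_w = gb_eps_w),
            class = "energy_config")
}

energy_breakdown <- function(vdw, elec, polar, nonpolar, entropy, w) {
  terms <- c(vdw = vdw, electrostatic_coulomb = elec,
             polar_solvation_gb = polar, nonpolar_sasa = nonpolar,
             sidechain_entropy = entropy)
  wt <- sum(terms * c(w$vdw, w$elec, w$polar, w$nonpolar, w$entropy))
  structure(c(as.list(terms), list(weighted_total = wt)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<energy_breakdown> vdw %.3f  elec %.3f  gb %.3f  ",
                     "sasa %.3f  entropy %.3f  | weighted %.3f kcal/mol\n"),
              x$vdw, x$electrostatic_coulomb, x$polar_solvation_gb,
              x$nonpolar_sasa, x$sidechain_entropy, x$weighted_total))
  invisible(x)
}

# per-atom inputs for the compiled kernels; residues failing the backbone
# check are excluded from energetics
energy_atoms <- function(s) {
  a <- s$atoms[s$atoms$complete_bb, , drop = FALSE]
  if (!nrow(a)) stopf("no residues pass the backbone completeness check")
  p <- atom_params(a$resid, a$elety)
  key <- paste(a$chain, a$resno, a$insert)
  res_idx <- a$resno
  chain_idx <- as.integer(factor(a$chain, levels = unique(a$chain)))
  list(a = a, xyz = as.matrix(a[, c("x", "y", "z")]),
       eps = p$eps, rmin = p$rmin, q = p$charge, rho = p$rho,
       res = as.integer(res_idx), chain = chain_idx,
       bbcb = as.integer(a$elety %in% c(BACKBONE_ATOMS, "CB")),
       reskey = key)
}

#' Folding-energy terms of a structure
#'
#' Computes the five energy terms of the simplified force field:
#' Lennard-Jones 6-12 over non-bonded heavy-atom pairs, Coulomb
#' electrostatics with distance-dependent dielectric, Still-style
#' Generalized-Born polar solvation, gamma*SASA nonpolar solvation, and a
#' per-residue side-chain rotamer-entropy term.  All parameters come from
#' the bundled tables; the result is bitwise-stable for a given
#' configuration.
#'
#' @param s a [fab_structure()].
#' @param w a [term_weights()].
#' @param config an [energy_config()].
#' @return an `energy_breakdown` (kcal/mol).
#' @export
fold_energy <- function(s, w = term_weights(), config = energy_config()) {
  e <- energy_atoms(s)
  nb <- .nonbonded_cpp(e$xyz, e$eps, e$rmin, e$q, e$res, e$chain, e$bbcb,
                       config$switch_on, config$cutoff, config$diel_factor)
  gb <- .gb_cpp(e$xyz, e$q, e$rho, config$switch_on, config$cutoff,
                config$gb_descreen, config$gb_descreen_scale,
                config$gb_alpha_max, config$gb_eps_w)
  sasa <- sum(.sasa_cpp(e$xyz, e$rho, config$probe, config$sasa_points))
  resid1 <- e$a$resid[!duplicated(e$reskey)]
  ent <- sum(residue_entropy(resid1))
  energy_breakdown(nb$vdw, nb$elec, gb, config$gamma * sasa, ent, w)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley SASA with the scanner's deterministic point set; exposed for
#' burial analysis of generated structures.
#'
#' @inheritParams fold_energy
#' @return data frame with one row per atom (chain, resno, resid, elety, sasa).
#' @export
atom_sasa <- function(s, config = energy_config()) {
  e <- energy_atoms(s)
  cbind(e$a[, c("chain", "resno", "insert", "resid", "elety")],
        sasa = as.numeric(.sasa_cpp(e$xyz, e$rho, config$probe,
                                    config$sasa_points)))
}

#' Relative per-residue SASA
#'
#' Residue SASA divided by the bundled Gly-X-Gly maximum for that residue
#' type, as a percentage.
#'
#' @inheritParams fold_energy
#' @return data frame: chain, resno, resid, sasa, rel_sasa (percent).
#' @export
residue_rel_sasa <- function(s, config = energy_config()) {
  at <- atom_sasa(s, config)
  key <- paste(at$chain, at$resno, at$insert)
  tot <- tapply(at$sasa, factor(key, levels = unique(key)), sum)
  first <- !duplicated(key)
  mx <- param_table("max_sasa")
  res <- at$resid[first]
  data.frame(chain = at$chain[first], resno = at$resno[first], resid = res,
             sasa = as.numeric(tot),
             rel_sasa = 100 * as.numeric(tot) / mx$max_sasa[match(res, mx$resid)],
             stringsAsFactors = FALSE)
}

# unfolded-state reference: extended tripeptide centred on the site
tripeptide_window <- function(s, chain, position) {
  r <- fab_residues(s)
  r <- r[r$chain == chain, , drop = FALSE]
  i <- which(r$resno == position)
  if (!length(i)) stopf("residue %s%d not found", chain, position)
  idx <- max(1, i - 1):min(nrow(r), i + 1)
  list(seq = aa_one(r$resid[idx]), centre = which(idx == i))
}

unfolded_reference <- function(seq1, w, config) {
  s <- build_extended_peptide(seq1)
  fold_energy(s, w, config)
}

#' Mutation energy (ddG) of one or more substitutions in one context
#'
#' ddG = (E_folded(mut) - E_unfolded(mut)) - (E_folded(wt) - E_unfolded(wt)),
#' where the unfolded reference of each site is an isolated extended
#' tripeptide (site +/- 1) evaluated with the same terms.  The side-chain
#' entropy term enters through the folded structures only (the unfolded
#' state's side chains are taken as unrestricted).  Positive values are
#' destabilizing.  Several mutations may be passed at once provided their
#' tripeptide windows do not overlap; their unfolded references are summed.
#'
#' @param s a [fab_structure()] (the context: parental or humanized).
#' @param m a [point_mutation()] or list of them.
#' @param w a [term_weights()].
#' @param config an [energy_config()].
#' @param chain_map mapping of HC/LC to PDB chain ids.
#' @param folded_wt optional precomputed `fold_energy(s, w, config)`, reused
#'   across calls when scanning many candidates on the same structure.
#' @return list with `ddg` (weighted total, kcal/mol), `breakdown` (named
#'   per-term ddG vector) and the mutant structure.
#' @export
mutation_energy <- function(s, m, w = term_weights(), config = energy_config(),
                            chain_map = c(HC = "H", LC = "L"),
                            folded_wt = NULL) {
  if (inherits(m, "point_mutation")) m <- list(m)
  pos <- vapply(m, function(x) paste(x$chain, x$position), character(1))
  if (anyDuplicated(pos)) stopf("duplicate mutation sites")
  if (length(m) > 1) {
    pp <- vapply(m, function(x) x$position, numeric(1))
    cc <- vapply(m, function(x) x$chain, character(1))
    ov <- outer(pp, pp, function(a, b) abs(a - b) <= 2) &
      outer(cc, cc, "==") & !diag(length(m))
    if (any(ov)) stopf("tripeptide windows of the mutations overlap")
  }
  ef_wt <- folded_wt %||% fold_energy(s, w, config)
  smut <- s
  for (mm in m) smut <- build_mutant_structure(smut, mm, chain_map)
  ef_mut <- fold_energy(smut, w, config)
  terms <- c("vdw", "electrostatic_coulomb", "polar_solvation_gb",
             "nonpolar_sasa", "sidechain_entropy")
  dd <- unlist(ef_mut[terms]) - unlist(ef_wt[terms])
  for (mm in m) {
    if (mm$identity) next  # identical tripeptide references cancel exactly
    ch <- chain_map[[mm$chain]]
    win_wt <- tripeptide_window(s, ch, mm$position)
    win_mut <- win_wt$seq
    win_mut[win_wt$centre] <- mm$mut_aa
    eu_wt <- unfolded_reference(win_wt$seq, w, config)
    eu_mut <- unfolded_reference(win_mut, w, config)
    du <- unlist(eu_mut[terms]) - unlist(eu_wt[terms])
    du["sidechain_entropy"] <- 0  # unfolded side chains unrestricted
    dd <- dd - du
  }
  wv <- c(w$vdw, w$elec, w$polar, w$nonpolar, w$entropy)
  list(ddg = sum(dd * wv), breakdown = dd, mutant = smut)
}

#' Scan candidate mutations in both structural contexts
#'
#' Evaluates every candidate in the parental (murine) structure and in the
#' humanized model, producing one [mutation_record()] per candidate with both
#' contexts filled.  Per-candidate failures are collected and reported; the
#' scan continues.
#'
#' @param s_parental,s_humanized the two context structures.
#' @param candidates list of [point_mutation()].
#' @param w a [term_weights()].
#' @param config an [energy_config()].
#' @param chain_map mapping of HC/LC to PDB chain ids.
#' @return list with `records` (list of `mutation_record`, input order) and
#'   `failures` (named character vector of error messages).
#' @export
scan_mutations <- function(s_parental, s_humanized, candidates,
                           w = term_weights(), config = energy_config(),
                           chain_map = c(HC = "H", LC = "L")) {
  records <- list()
  failures <- character()
  ef_par <- fold_energy(s_parental, w, config)
  ef_hum <- fold_energy(s_humanized, w, config)
  for (m in candidates) {
    r <- tryCatch({
      ep <- mutation_energy(s_parental, m, w, config, chain_map, folded_wt = ef_par)
      eh <- mutation_energy(s_humanized, m, w, config, chain_map, folded_wt = ef_hum)
      mutation_record(m, ddg_parental = ep$ddg, ddg_model = eh$ddg,
                      breakdown_parental = ep$breakdown,
                      breakdown_model = eh$breakdown)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      failures[format(m)] <- conditionMessage(r)
    } else {
      records[[length(records) + 1]] <- r
    }
  }
  list(records = records, failures = failures)
}

#' A candidate mutation with its two-context energies
#'
#' Row type of the candidate tables: a point mutation plus its ddG in the
#' parental murine structure and in the humanized model.  At least one
#' context must be populated; positive = destabilizing.
#'
#' @param mutation a [point_mutation()].
#' @param ddg_parental,ddg_model ddG (kcal/mol) per context (NA if absent).
#' @param direction `"back"` (restores the murine residue) or `"humanizing"`.
#' @param breakdown_parental,breakdown_model optional per-term vectors.
#' @return object of class `mutation_record`.
#' @export
mutation_record <- function(mutation, ddg_parental = NA_real_,
                            ddg_model = NA_real_, direction = NA_character_,
                            breakdown_parental = NULL, breakdown_model = NULL) {
  stopifnot(inherits(mutation, "point_mutation"))
  if (is.na(ddg_parental) && is.na(ddg_model))
    stopf("mutation record %s has neither context populated", format(mutation))
  structure(list(mutation = mutation, ddg_parental = ddg_parental,
                 ddg_model = ddg_model, direction = direction,
                 breakdown_parental = breakdown_parental,
                 breakdown_model = breakdown_model),
            class = "mutation_record")
}

#' @export
print.mutation_record <- function(x, ...) {
  cat(sprintf("<mutation_record> %s  parental %+.2f  model %+.2f  (%s)\n",
              format(x$mutation), x$ddg_parental, x$ddg_model,
              x$direction %||% "?"))
  invisible(x)
}
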