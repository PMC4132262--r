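# deterministic toy Fab generator: a two-chain four-helix mini-domain that
# exercises the scanner's code paths.  It is NOT a real antibody fold and is
# documented as such; it exists so that structure-based stages run at desk
# scale with buried and exposed test sites.

# rigid transform mapping the principal axis of a residue coordinate set onto
# a target axis through a target point
.align_helix <- function(res_list, origin, up = TRUE) {
  ca <- do.call(rbind, lapply(res_list, function(r) r$CA))
  ctr <- colMeans(ca)
  ax <- svd(sweep(ca, 2, ctr))$v[, 1]
  if ((ca[nrow(ca), 3] - ca[1, 3]) * ax[3] < 0) ax <- -ax  # follow chain dir
  target <- if (up) c(0, 0, 1) else c(0, 0, -1)
  v <- vcross(ax, target)
  s <- sqrt(sum(v^2)); cc <- sum(ax * target)
  R <- diag(3)
  if (s > 1e-12) {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
  } else if (cc < 0) R <- diag(c(1, -1, -1))
  lapply(res_list, function(r)
    lapply(r, function(p) as.numeric(R %*% (p - ctr)) + origin))
}

# backbone for one loop residue from its CA and local tangent
.loop_backbone <- function(ca, tangent, normal) {
  t <- vnormalize(tangent); nrm <- vnormalize(normal - sum(normal * t) * t)
  list(N = ca - 1.05 * t + 0.45 * nrm,
       CA = ca,
       C = ca + 1.10 * t + 0.40 * nrm,
       O = ca + 1.35 * t + 1.55 * nrm)
}

#' Generate the deterministic toy Fab structure
#'
#' Builds a two-chain mini-domain (60 residues per chain): two idealized
#' antiparallel alpha-helices per chain joined by a short loop, the four
#' helices packed as a square bundle.  Core-facing helix positions carry
#' leucine so the bundle has a hydrophobic interior; surface positions cycle
#' through polar/charged residues.  Side chains are packed by the scanner's
#' own minimum-clash rotamer rule, so every residue passes the backbone
#' completeness check.  A small seeded coordinate jitter (0.02 A) breaks
#' exact symmetry; the same seed always returns the identical structure.
#'
#' This is a synthetic stand-in used to exercise code paths and invariants,
#' not a model of any real antibody.
#'
#' @param seed integer seed.
#' @return a [fab_structure()] with attributes `buried_sites` and
#'   `exposed_sites` (data frames of chain/resno with relative SASA below 10
#'   percent and above 40 percent).
#' @export
make_toy_fab <- function(seed = 1) {
  h_len <- 26; loop_len <- 6
  n_res <- 60
  spacing <- 10.6
  centre_xy <- c(spacing / 2, spacing / 2)
  chains <- list(H = c(0, 0), L = c(0, spacing))

  atoms <- list()
  axis_xy <- list()
  for (ch in names(chains)) {
    y0 <- chains[[ch]][2]
    a1 <- c(0, y0); a2 <- c(spacing, y0)
    helix1 <- .align_helix(build_backbone_coords(h_len, -57, -47),
                           c(a1, 39 / 2), up = TRUE)
    helix2 <- .align_helix(build_backbone_coords(n_res - h_len - loop_len, -57, -47),
                           c(a2, 39 / 2), up = FALSE)
    # loop CAs on an elliptical arc above the helices
    p0 <- helix1[[h_len]]$CA; p1 <- helix2[[1]]$CA
    tt <- seq(0, pi, length.out = loop_len + 2)[2:(loop_len + 1)]
    mid <- (p0 + p1) / 2
    span <- (p1 - p0) / 2
    ztop <- max(p0[3], p1[3]) + 8
    loop <- vector("list", loop_len)
    ca_prev <- p0
    for (k in seq_len(loop_len)) {
      ca <- mid - span * cos(tt[k]) + c(0, 0, (ztop - mid[3]) * sin(tt[k]))
      ca_next <- if (k < loop_len)
        mid - span * cos(tt[k + 1]) + c(0, 0, (ztop - mid[3]) * sin(tt[k + 1]))
      else p1
      loop[[k]] <- .loop_backbone(ca, ca_next - ca_prev, c(0, 0, 1))
      ca_prev <- ca
    }
    res_list <- c(helix1, loop, helix2)
    helix_axis <- c(rep(list(a1), h_len), rep(list(NULL), loop_len),
                    rep(list(a2), n_res - h_len - loop_len))
    atoms[[ch]] <- res_list
    axis_xy[[ch]] <- helix_axis
  }

  # sequence assignment from geometry: core-facing helix positions get LEU
  surface_cycle <- c("SER", "GLU", "ALA", "LYS", "THR", "ALA", "GLN")
  rows <- list()
  for (ch in names(atoms)) {
    res_list <- atoms[[ch]]
    for (i in seq_along(res_list)) {
      ax <- axis_xy[[ch]][[i]]
      if (is.null(ax)) {
        res3 <- if (i %% 2 == 0) "GLY" else "SER"
      } else {
        ca <- res_list[[i]]$CA
        out_dir <- vnormalize(c(ca[1] - ax[1], ca[2] - ax[2], 0))
        to_centre <- vnormalize(c(centre_xy - ax, 0))
        res3 <- if (sum(out_dir * to_centre) > 0.55) {
          if (i %% 2 == 0) "LEU" else "VAL"
        }
        else surface_cycle[(i - 1) %% length(surface_cycle) + 1]
      }
      b <- res_list[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, resno = i, insert = "", resid = res3,
        elety = BACKBONE_ATOMS,
        x = c(b$N[1], b$CA[1], b$C[1], b$O[1]),
        y = c(b$N[2], b$CA[2], b$C[2], b$O[2]),
        z = c(b$N[3], b$CA[3], b$C[3], b$O[3]),
        occ = 1, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # seeded symmetry-breaking jitter
  old <- .Random.seed_save()
  set.seed(seed)
  tab[, c("x", "y", "z")] <- tab[, c("x", "y", "z")] +
    stats::rnorm(nrow(tab) * 3, sd = 0.02)
  .Random.seed_restore(old)

  s <- fab_structure(tab)
  # pack side chains residue by residue with the minimum-clash rotamer rule
  for (ch in names(atoms)) {
    for (i in seq_len(n_res)) {
      rws <- residue_rows(s, ch, i)
      res3 <- s$atoms$resid[rws[1]]
      if (res3 == "GLY") next
      bb <- residue_backbone(s, rws)
      env <- clash_environment(s, ch, i)
      pick <- place_best_rotamer(res3, bb, env)
      sc <- pick$atoms
      if (!length(sc)) next
      xyz <- do.call(rbind, sc)
      add <- data.frame(chain = ch, resno = i, insert = "", resid = res3,
                        elety = names(sc), x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], occ = 1, complete_bb = TRUE,
                        stringsAsFactors = FALSE)
      a <- s$atoms
      before <- a[seq_len(max(rws)), , drop = FALSE]
      after <- if (max(rws) < nrow(a)) a[(max(rws) + 1):nrow(a), , drop = FALSE] else NULL
      s$atoms <- rbind(before, add, after)
      rownames(s$atoms) <- NULL
    }
  }
  rs <- residue_rel_sasa(s)
  attr(s, "buried_sites") <- rs[rs$rel_sasa < 10, c("chain", "resno", "resid")]
  attr(s, "exposed_sites") <- rs[rs$rel_sasa > 40, c("chain", "resno", "resid")]
  s
}

# save/restore the global RNG state so generators are pure functions of seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
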