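# synthetic-data generators for sequences and assay curves.  All generators
# are pure functions of (config, seed): the global RNG state is saved and
# restored around every draw.

# germline-like synthetic V-region templates (heavy: IGHV3-33-style,
# light: IGKV3-15-style) with region annotations.  These are synthetic
# stand-ins assembled for testing, not database sequences.
.template_defs <- list(
  heavy = list(
    segments = c(FR1 = "QVQLVESGGGVVQPGRSLRLSCAAS",
                 CDR1 = "GFTFSSYGMH",
                 FR2 = "WVRQAPGKGLEWVA",
                 CDR2 = "VIWYDGSNKYYADSVK",
                 FR3 = "GRFTISRDNSKNTLYLQMNSLRAEDTAVYYCA",
                 CDR3 = "RDYYGSGSYF",
                 FR4 = "DYWGQGTLVTV")),
  light = list(
    segments = c(FR1 = "EIVMTQSPATLSVSPGERATLSC",
                 CDR1 = "RASQSVSSNLA",
                 FR2 = "WYQQKPGQAPRLLIY",
                 CDR2 = "GASTRAT",
                 FR3 = "GIPARFSGSGSGTEFTLTISSLQSEDFAVYYC",
                 CDR3 = "QQYNNWPPT",
                 FR4 = "FGQGTKLEIK")))

#' Germline-like synthetic V-region template
#'
#' Returns the bundled heavy- or light-chain template as an annotated
#' [v_region()] (region map from the template's segment boundaries).
#'
#' @param chain_kind `"heavy"` or `"light"`.
#' @return a `v_region`.
#' @export
germline_template <- function(chain_kind = c("heavy", "light")) {
  chain_kind <- match.arg(chain_kind)
  seg <- .template_defs[[chain_kind]]$segments
  labels <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  rmap <- rep(labels, nchar(seg))
  v_region(paste(seg, collapse = ""), chain_kind, region_map = rmap,
           name = paste0("template_", chain_kind))
}

#' Generate a synthetic human V-sequence database
#'
#' Emulates a human antibody V-region database at desk scale: `n` sequences
#' derived from the bundled germline-like templates by seeded point
#' substitutions (per-position probability `substitution_rate`, replacement
#' drawn uniformly from the other 19 residues).  Same seed, same FASTA
#' bytes.
#'
#' @param n number of sequences (>= 1).
#' @param chain_kind template to mutate (`"heavy"` or `"light"`), or
#'   `"both"` to alternate.
#' @param substitution_rate per-position substitution probability in
#'   \[0, 0.3\].
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
make_human_v_db <- function(n, chain_kind = "heavy", substitution_rate = 0.05,
                            seed = 1) {
  if (n < 1) stopf("n must be >= 1")
  if (substitution_rate < 0 || substitution_rate > 0.3)
    stopf("substitution_rate must lie in [0, 0.3]")
  kinds <- if (chain_kind == "both")
    rep(c("heavy", "light"), length.out = n) else rep(chain_kind, n)
  old <- .Random.seed_save()
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    res <- strsplit(as.character(germline_template(kinds[i])), "")[[1]]
    hit <- stats::runif(length(res)) < substitution_rate
    for (j in which(hit)) res[j] <- sample(setdiff(AA1, res[j]), 1)
    paste(res, collapse = "")
  }, character(1))
  .Random.seed_restore(old)
  names(out) <- sprintf("%s_%04d", substr(kinds, 1, 1), seq_len(n))
  out
}

#' Simulate a triplicate ADCC dose-response table
#'
#' Variable-slope 4PL lysis curves over a log-spaced concentration series
#' with seeded Gaussian noise per replicate.
#'
#' @param params list with bottom, top, ec50 (ug/mL), hill.
#' @param concentrations ug/mL (default 8 half-log steps spanning the EC50).
#' @param n_replicates replicates per concentration.
#' @param noise_sd Gaussian noise on lysis, percentage points.
#' @param seed integer seed.
#' @param sample sample name.
#' @return a [dose_response()].
#' @export
simulate_dose_response <- function(params, concentrations = NULL,
                                   n_replicates = 3, noise_sd = 3, seed = 1,
                                   sample = "sample") {
  if (is.null(concentrations))
    concentrations <- 10^seq(-5, -0.5, length.out = 8)
  logx <- rep(log10(concentrations), each = n_replicates)
  mu <- four_pl(logx, params$bottom, params$top, log10(params$ec50),
                params$hill)
  old <- .Random.seed_save()
  set.seed(seed)
  y <- mu + stats::rnorm(length(mu), sd = noise_sd)
  .Random.seed_restore(old)
  dose_response(10^logx, y,
                replicate_id = rep(seq_len(n_replicates),
                                   times = length(concentrations)),
                sample = sample)
}

#' Generate a complete synthetic assay bundle
#'
#' Produces the three validation-assay data sets for one construct under
#' stated true parameters: bivalent-analyte sensorgrams over a 50-1600 nM
#' twofold dilution series (2 min association, 300 s dissociation), melt
#' curves on a 25-99 degree grid with Fab and Fc transitions in triplicate,
#' and a triplicate 4PL dose-response table.  All noise is Gaussian and
#' seeded.
#'
#' @param kinetics a [kinetic_params()].
#' @param melt_transitions transitions for [simulate_melt()] (default: Fab
#'   at 73.6 and Fc at 82 degrees C).
#' @param adcc 4PL parameters for [simulate_dose_response()].
#' @param noise list with `spr` (RU, absolute SD), `melt` (signal SD),
#'   `lysis` (percentage points).
#' @param seed integer seed.
#' @return list with `sensorgrams` (list of 6 [sensorgram()]s), `melt`
#'   (list of 3 [melt_curve()]s), `adcc` (a [dose_response()]), and the
#'   generating parameters.
#' @export
make_assay_bundle <- function(kinetics = kinetic_params(k_on = 1.09e5,
                                                        k_off = 1.25e-3,
                                                        k_on2 = 1e-4,
                                                        k_off2 = 1e-3,
                                                        R_max = 100),
                              melt_transitions = data.frame(
                                tm = c(73.6, 82), amplitude = c(100, 60),
                                slope = c(1, 1)),
                              adcc = list(bottom = 5, top = 65,
                                          ec50 = 2.61e-3, hill = 1.2),
                              noise = list(spr = 0, melt = 0, lysis = 0),
                              seed = 1) {
  concs <- c(50, 100, 200, 400, 800, 1600) * 1e-9
  grid <- seq(0, 420, by = 1.5)
  sens <- lapply(seq_along(concs), function(i) {
    s <- simulate_bivalent(kinetics, concs[i], grid, t_assoc_end = 120)
    if (noise$spr > 0) {
      old <- .Random.seed_save()
      set.seed(seed * 1000L + i)
      s$response <- s$response + stats::rnorm(nrow(s), sd = noise$spr)
      .Random.seed_restore(old)
    }
    s
  })
  melt <- lapply(1:3, function(r)
    simulate_melt(melt_transitions, baseline = c(10, 0.05),
                  noise_sd = noise$melt, seed = seed * 100L + r,
                  replicate_id = r))
  dr <- simulate_dose_response(adcc, noise_sd = max(noise$lysis, 1e-12),
                               seed = seed)
  list(sensorgrams = sens, melt = melt, adcc = dr,
       true = list(kinetics = kinetics, melt_transitions = melt_transitions,
                   adcc = adcc), seed = seed)
}
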