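# assay-table readers/writers and the end-to-end pipeline driver

#' Read sensorgrams from CSV
#'
#' Expected columns: `time`, `response`, `concentration` (M), and either
#' `t_assoc_end` or a `phase` column (`association`/`dissociation`); one
#' curve per concentration.
#'
#' @param file CSV path.
#' @return list of [sensorgram()]s.
#' @export
read_sensorgram_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time", "response", "concentration")
  if (!all(need %in% names(df)))
    stopf("sensorgram CSV must have columns %s", paste(need, collapse = ", "))
  lapply(split(df, df$concentration), function(d) {
    d <- d[order(d$time), ]
    ta <- if ("t_assoc_end" %in% names(d)) d$t_assoc_end[1]
    else if ("phase" %in% names(d)) max(d$time[d$phase == "association"])
    else stopf("sensorgram CSV needs a t_assoc_end or phase column")
    sensorgram(d$time, d$response, d$concentration[1], ta)
  })
}

#' Write sensorgrams to CSV
#' @param curves list of [sensorgram()]s.
#' @param file output path.
#' @export
write_sensorgram_csv <- function(curves, file) {
  if (inherits(curves, "sensorgram")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(s)
    data.frame(time = s$time, response = s$response,
               concentration = attr(s, "concentration"),
               t_assoc_end = attr(s, "t_assoc_end"))))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read melt curves from CSV (columns temperature, fluorescence, replicate
#' and optionally sample)
#' @param file CSV path.
#' @return named list (by sample) of lists of [melt_curve()]s.
#' @export
read_melt_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("temperature", "fluorescence", "replicate")
  if (!all(need %in% names(df)))
    stopf("melt CSV must have columns %s", paste(need, collapse = ", "))
  if (is.null(df$sample)) df$sample <- "sample"
  lapply(split(df, df$sample), function(d)
    lapply(split(d, d$replicate), function(r) {
      r <- r[order(r$temperature), ]
      melt_curve(r$temperature, r$fluorescence, r$replicate[1])
    }))
}

#' Read dose-response tables from CSV (columns sample, concentration,
#' replicate, lysis)
#' @param file CSV path.
#' @return named list of [dose_response()]s, one per sample.
#' @export
read_dose_response_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample", "concentration", "replicate", "lysis")
  if (!all(need %in% names(df)))
    stopf("dose-response CSV must have columns %s", paste(need, collapse = ", "))
  lapply(split(df, df$sample), function(d)
    dose_response(d$concentration, d$lysis, d$replicate, d$sample[1]))
}

.pipeline_stage_keys <- c("design", "humanness", "epitope", "spr", "dsf", "adcc")

validate_pipeline_config <- function(config) {
  known <- c("seed", "out", .pipeline_stage_keys)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stopf("unknown config keys: %s",
                             paste(unknown, collapse = ", "))
  for (st in .pipeline_stage_keys) {
    cfg <- config[[st]]
    if (is.null(cfg)) next
    for (f in intersect(names(cfg),
                        c("candidates", "ablations", "query", "db", "regions",
                          "matrix", "curves")))
      if (is.character(cfg[[f]]) && !cfg[[f]] %in%
          c("table1_v3", "table2_v5") && !file.exists(cfg[[f]]))
        stopf("stage %s: file not found: %s", st, cfg[[f]])
  }
  invisible(config)
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(fun(), error = function(e)
    structure(list(error = conditionMessage(e)), class = "stage_error"))
  if (inherits(res, "stage_error")) {
    report$errors[[name]] <- res$error
  } else {
    report$stages[[name]] <- res
  }
  report
}

#' Run the full refinement/analysis pipeline
#'
#' Executes the configured stages in the study's order — mutation-table
#' design, humanness and epitope analysis of the designed constructs, then
#' the three assay fits (SPR kinetics, thermal stability, ADCC) — and
#' returns a reproducible JSON-serialisable report embedding the seed and
#' the config.  Stage errors are recorded and later independent stages are
#' still attempted.
#'
#' @param config named list (or path to a JSON config file) with optional
#'   entries:
#'   * `seed`: integer;
#'   * `design`: `candidates` (CSV path or `"table1_v3"`/`"table2_v5"`),
#'     `mode` (`"v3"`/`"v5"`), `ablations` (CSV path, optional);
#'   * `humanness`: `query` (FASTA), `db` (FASTA), `regions` (CSV, optional);
#'   * `epitope`: `query` (FASTA), `matrix` (CSV, optional), `thresholds`;
#'   * `spr`: `curves` (CSV);
#'   * `dsf`: `curves` (CSV), `range` (optional Fab window, default 60-85);
#'   * `adcc`: `curves` (CSV), `compare` (two sample names, optional);
#'   * `out`: path for the JSON report (optional).
#' @return report list: `seed`, `config`, `package_version`, `stages`,
#'   `errors`, `status` (0 ok, 3 if any stage failed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_pipeline_config(config)
  seed <- config$seed %||% 1L
  report <- list(seed = seed, config = config,
                 package_version = as.character(utils::packageVersion("abrefine")),
                 stages = list(), errors = list())

  if (!is.null(config$design)) {
    report <- run_stage(report, "design", function() {
      cfg <- config$design
      cand <- read_candidate_table(cfg$candidates)
      abl <- NULL
      if (identical(cfg$mode, "v5"))
        abl <- if (is.null(cfg$ablations)) v5_epitope_ablations()
        else {
          df <- utils::read.csv(cfg$ablations, stringsAsFactors = FALSE)
          lapply(df$mutation, parse_mutation)
        }
      d <- design_construct(cand, design_rules(), epitope_ablations = abl,
                            name = cfg$mode %||% "construct")
      list(name = d$name, n_mutations = length(d$mutations),
           mutations = vapply(d$mutations, function(r) format(r$mutation),
                              character(1)),
           phenotype = d$phenotype_per_mutation,
           net_energy_murine_context = d$net_energy_murine_context,
           net_energy_humanized_context = d$net_energy_humanized_context)
    })
  }
  if (!is.null(config$humanness)) {
    report <- run_stage(report, "humanness", function() {
      cfg <- config$humanness
      regions <- if (!is.null(cfg$regions)) read_region_annotations(cfg$regions)
      qs <- read_vregion_fasta(cfg$query, regions)
      db <- read_vregion_fasta(cfg$db)
      db <- stats::setNames(vapply(db, as.character, character(1)), names(db))
      lapply(qs, function(q) {
        r <- humanness_report(q, db)
        list(t20_full = r$t20_full, t20_framework = r$t20_framework)
      })
    })
  }
  if (!is.null(config$epitope)) {
    report <- run_stage(report, "epitope", function() {
      cfg <- config$epitope
      m <- if (is.null(cfg$matrix)) toy_epitope_matrix()
      else read_epitope_matrix(cfg$matrix)
      thr <- cfg$thresholds %||% c(6, 3)
      qs <- read_vregion_fasta(cfg$query)
      lapply(qs, function(q) scan_epitopes(q, m, thr))
    })
  }
  if (!is.null(config$spr)) {
    report <- run_stage(report, "spr", function() {
      curves <- read_sensorgram_csv(config$spr$curves)
      fit <- fit_bivalent(curves)
      list(k_on = fit$params$k_on, k_off = fit$params$k_off,
           k_on2 = fit$params$k_on2, k_off2 = fit$params$k_off2,
           R_max = fit$params$R_max, rss = fit$rss,
           kd_nM = equilibrium_kd(fit))
    })
  }
  if (!is.null(config$dsf)) {
    report <- run_stage(report, "dsf", function() {
      cfg <- config$dsf
      rng <- cfg$range %||% c(60, 85)
      samples <- read_melt_csv(cfg$curves)
      lapply(samples, function(reps) {
        tms <- vapply(reps, function(cv) {
          pk <- tm_derivative(cv, range = rng)
          if (!nrow(pk)) NA_real_ else pk$tm[1]
        }, numeric(1))
        list(tm_replicates = unname(tms), tm_mean = mean(tms, na.rm = TRUE),
             tm_sd = stats::sd(tms[!is.na(tms)]))
      })
    })
  }
  if (!is.null(config$adcc)) {
    report <- run_stage(report, "adcc", function() {
      cfg <- config$adcc
      samples <- read_dose_response_csv(cfg$curves)
      fits <- lapply(samples, fit_4pl)
      out <- lapply(fits, function(f)
        list(ec50 = f$ec50, hill = f$hill, bottom = f$bottom, top = f$top,
             rss = f$rss))
      if (!is.null(cfg$compare) && length(cfg$compare) == 2) {
        a <- cfg$compare[1]; b <- cfg$compare[2]
        cmp <- compare_ec50(samples[[a]], samples[[b]], fits[[a]], fits[[b]])
        out$comparison <- list(samples = cfg$compare, F = cmp$F,
                               p_value = cmp$p_value,
                               relative_potency =
                                 relative_potency(fits[[a]]$ec50, fits[[b]]$ec50))
      }
      out
    })
  }
  report$status <- if (length(report$errors)) 3L else 0L
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}
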