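# mutation-selection rules for framework variant design
#
# The selection criteria are narrated, not stated formally, in the source
# tables; the predicates below are the minimal rule system consistent with
# every row of the bundled candidate tables.  Which clause fired is recorded
# on every decision so alternative reconstructions can be compared.

#' Design rules for mutation selection
#'
#' * Back mutations (restoring the murine residue) are accepted when they
#'   stabilize the parental murine structure (`ddg_parental < 0`; the
#'   experimentally determined crystal structure is weighted over the
#'   homology model), when they strongly stabilize the humanized model
#'   (`ddg_model < -strong_model_stabilization`), or when they involve Gly or
#'   Pro, which can affect backbone conformation.
#' * Humanizing mutations are accepted when, in each context, they either
#'   enhance stability or have a negligible effect
#'   (`ddg < negligible_threshold` in both contexts).
#'
#' The strong-model-stabilization clause is a reconstruction: it exists to
#' admit back mutations that are near-neutral in the parental context but
#' clearly stabilizing in the model; its threshold is exposed here.
#'
#' @param negligible_threshold kcal/mol below which an effect is negligible
#'   (default 0.5).
#' @param strong_model_stabilization kcal/mol of model-context stabilization
#'   that justifies a back mutation on its own (default 0.5).
#' @param emphasize_parental_context keep the parental-context test primary.
#' @param glycine_proline_backmutation accept Gly/Pro back mutations
#'   regardless of energy.
#' @return list of class `design_rules`.
#' @export
design_rules <- function(negligible_threshold = 0.5,
                         strong_model_stabilization = 0.5,
                         emphasize_parental_context = TRUE,
                         glycine_proline_backmutation = TRUE) {
  if (negligible_threshold < 0 || strong_model_stabilization < 0)
    stopf("thresholds must be >= 0")
  structure(list(negligible_threshold = negligible_threshold,
                 strong_model_stabilization = strong_model_stabilization,
                 emphasize_parental_context = emphasize_parental_context,
                 glycine_proline_backmutation = glycine_proline_backmutation),
            class = "design_rules")
}

decision <- function(mutation, action, rule_fired) {
  structure(list(mutation = mutation, action = action,
                 rule_fired = rule_fired), class = "design_decision")
}

#' @export
print.design_decision <- function(x, ...) {
  cat(sprintf("<decision> %s -> %s (%s)\n", format(x$mutation), x$action,
              x$rule_fired))
  invisible(x)
}

need_contexts <- function(rec) {
  if (is.na(rec$ddg_parental) || is.na(rec$ddg_model))
    stopf("record %s is missing a context energy", format(rec$mutation))
}

#' Classify a candidate back mutation
#'
#' @param rec a [mutation_record()] whose mutation restores the murine
#'   residue.
#' @param rules a [design_rules()].
#' @return a decision with action `revert_to_murine` or `exclude` and the
#'   rule that fired.
#' @export
classify_backmutation <- function(rec, rules = design_rules()) {
  need_contexts(rec)
  m <- rec$mutation
  if (rec$ddg_parental < 0)
    return(decision(m, "revert_to_murine", "parental-context stabilizing"))
  if (rec$ddg_model < -rules$strong_model_stabilization)
    return(decision(m, "revert_to_murine", "model-context strongly stabilizing"))
  if (rules$glycine_proline_backmutation &&
      (m$wt_aa %in% c("G", "P") || m$mut_aa %in% c("G", "P")))
    return(decision(m, "revert_to_murine", "Gly/Pro backbone"))
  decision(m, "exclude", "destabilizing back mutation")
}

#' Classify a candidate humanizing mutation
#'
#' Accepted when the mutation either enhances stability or has a negligible
#' effect (below the rules' threshold) in both the parental structure and
#' the humanized model.
#'
#' @inheritParams classify_backmutation
#' @return a decision with action `humanize` or `exclude`.
#' @export
classify_humanizing <- function(rec, rules = design_rules()) {
  need_contexts(rec)
  thr <- rules$negligible_threshold
  if (rec$ddg_parental < thr && rec$ddg_model < thr) {
    rule <- if (rec$ddg_parental <= 0 && rec$ddg_model <= 0)
      "stabilizing in both contexts" else "negligible or stabilizing"
    return(decision(rec$mutation, "humanize", rule))
  }
  decision(rec$mutation, "exclude", "destabilizing humanizing mutation")
}

#' Assemble a construct from classified candidates
#'
#' Applies [classify_backmutation()] / [classify_humanizing()] to every
#' candidate record (according to its `direction`) and collects the accepted
#' mutations into a construct with net mutation energies per context (exact
#' sums over the selected records).  Epitope-ablating mutations bypass the
#' energy gate: they are included regardless of their energies, as CDR
#' changes made to remove a predicted T-cell epitope.
#'
#' @param candidates list of [mutation_record()] with `direction` set to
#'   `"back"` or `"humanizing"`.
#' @param rules a [design_rules()].
#' @param epitope_ablations optional list of [point_mutation()] included
#'   regardless of energy (matched to candidate records by chain/position).
#' @param name construct name.
#' @return object of class `construct_design`: name, mutations (selected
#'   records), decisions (all candidates), net energies per context.
#' @export
design_construct <- function(candidates, rules = design_rules(),
                             epitope_ablations = NULL, name = "construct") {
  abl_keys <- character()
  if (!is.null(epitope_ablations)) {
    if (inherits(epitope_ablations, "point_mutation"))
      epitope_ablations <- list(epitope_ablations)
    abl_keys <- vapply(epitope_ablations,
                       function(m) paste(m$chain, m$position), character(1))
  }
  decisions <- list()
  selected <- list()
  phenotypes <- character()
  for (rec in candidates) {
    key <- paste(rec$mutation$chain, rec$mutation$position)
    if (key %in% abl_keys) {
      d <- decision(rec$mutation, "humanize", "epitope ablation")
    } else {
      d <- switch(rec$direction,
                  back = classify_backmutation(rec, rules),
                  humanizing = classify_humanizing(rec, rules),
                  stopf("candidate %s has unknown direction '%s'",
                        format(rec$mutation), rec$direction))
    }
    decisions[[length(decisions) + 1]] <- d
    if (d$action != "exclude") {
      selected[[length(selected) + 1]] <- rec
      phenotypes[length(selected)] <-
        if (d$action == "revert_to_murine") "Murine" else "Human"
    }
  }
  keys <- vapply(selected, function(r) paste(r$mutation$chain, r$mutation$position),
                 character(1))
  if (anyDuplicated(keys))
    stopf("duplicate chain/position among selected mutations: %s",
          keys[duplicated(keys)][1])
  structure(list(
    name = name,
    mutations = selected,
    phenotype_per_mutation = phenotypes,
    decisions = decisions,
    net_energy_murine_context = net_mutation_energy(selected, "parental"),
    net_energy_humanized_context = net_mutation_energy(selected, "model")),
    class = "construct_design")
}

#' @export
print.construct_design <- function(x, ...) {
  cat(sprintf("<construct_design> %s: %d mutations, net %+0.2f (parental) / %+0.2f (model) kcal/mol\n",
              x$name, length(x$mutations), x$net_energy_murine_context,
              x$net_energy_humanized_context))
  for (i in seq_along(x$mutations))
    cat(sprintf("  %-10s %-10s %+0.2f  %+0.2f  %s\n",
                format(x$mutations[[i]]$mutation),
                x$mutations[[i]]$mutation$location,
                x$mutations[[i]]$ddg_parental, x$mutations[[i]]$ddg_model,
                x$phenotype_per_mutation[i]))
  invisible(x)
}

#' Net mutation energy of a record set in one context
#'
#' Exact arithmetic sum over the records, reported to two decimals with
#' halves rounded away from zero (the tables' printed convention).
#'
#' @param records list of [mutation_record()].
#' @param context `"parental"` (murine structure) or `"model"` (humanized
#'   model).
#' @return net energy in kcal/mol (2 decimals).
#' @export
net_mutation_energy <- function(records, context = c("parental", "model")) {
  context <- match.arg(context)
  if (!length(records)) return(0)
  field <- if (context == "parental") "ddg_parental" else "ddg_model"
  vals <- vapply(records, function(r) {
    v <- r[[field]]
    if (is.na(v)) stopf("record %s is missing the %s context",
                        format(r$mutation), context)
    v
  }, numeric(1))
  round_half_away(sum(vals), 2)
}

#' Read a candidate-mutation table
#'
#' CSV columns: mutation (e.g. `"LC:E1S"`), location, ddg_parental,
#' ddg_model, direction (`back` or `humanizing`).  The bundled fixtures
#' `table1_v3.csv` and `table2_v5.csv` transcribe the published candidate
#' tables for the V3 and V5 designs.
#'
#' @param file CSV path, or one of the shorthand names `"table1_v3"`,
#'   `"table2_v5"` for the bundled fixtures.
#' @return list of [mutation_record()].
#' @export
read_candidate_table <- function(file) {
  if (file %in% c("table1_v3", "table2_v5"))
    file <- abr_file("tables", paste0(file, ".csv"))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("mutation", "ddg_parental", "ddg_model", "direction")
  if (!all(need %in% names(df)))
    stopf("candidate table must have columns %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    mutation_record(parse_mutation(df$mutation[i],
                                   location = df$location[i] %||% ""),
                    ddg_parental = df$ddg_parental[i],
                    ddg_model = df$ddg_model[i],
                    direction = df$direction[i]))
}

#' The bundled V5 epitope-ablation list (four CDR-H2 mutations)
#' @return list of [point_mutation()].
#' @export
v5_epitope_ablations <- function() {
  df <- utils::read.csv(abr_file("tables", "v5_epitope_ablations.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    parse_mutation(df$mutation[i], location = df$location[i]))
}
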