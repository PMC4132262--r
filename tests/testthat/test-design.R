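rec <- function(mut, dp, dm, direction = "back")
  mutation_record(parse_mutation(mut), ddg_parental = dp, ddg_model = dm,
                  direction = direction)

test_that("back-mutation classification fires the documented rules", {
  d1 <- classify_backmutation(rec("LC:S12L", -1.26, 0.79))
  expect_equal(d1$action, "revert_to_murine")
  expect_equal(d1$rule_fired, "parental-context stabilizing")

  d2 <- classify_backmutation(rec("LC:T10F", 0.17, -0.95))
  expect_equal(d2$action, "revert_to_murine")
  expect_equal(d2$rule_fired, "model-context strongly stabilizing")

  d3 <- classify_backmutation(rec("LC:Q100G", 1.06, 2.94))
  expect_equal(d3$action, "revert_to_murine")
  expect_equal(d3$rule_fired, "Gly/Pro backbone")

  # destabilizing in both, no Gly/Pro: excluded
  d4 <- classify_backmutation(rec("LC:A7V", 0.8, 0.2))
  expect_equal(d4$action, "exclude")

  # Gly/Pro rule can be switched off
  d5 <- classify_backmutation(rec("LC:Q100G", 1.06, 2.94),
                              design_rules(glycine_proline_backmutation = FALSE))
  expect_equal(d5$action, "exclude")

  expect_error(classify_backmutation(
    mutation_record(parse_mutation("LC:E1S"), ddg_parental = -0.5,
                    direction = "back")), "missing")
})

test_that("humanizing classification accepts stabilizing-or-negligible only", {
  expect_equal(classify_humanizing(rec("LC:K24R", -0.21, -0.17, "humanizing"))$action,
               "humanize")
  expect_equal(classify_humanizing(rec("HC:I20L", 0.43, -0.86, "humanizing"))$action,
               "humanize")
  # stabilizing in one context, negligible in the other
  expect_equal(classify_humanizing(rec("LC:V58I", -0.64, 0.01, "humanizing"))$action,
               "humanize")
  expect_equal(classify_humanizing(rec("HC:A1S", 1.2, 0.8, "humanizing"))$action,
               "exclude")
  # threshold is strict
  expect_equal(classify_humanizing(rec("HC:A1S", 0.5, 0.0, "humanizing"))$action,
               "exclude")
})

test_that("the V3 fixture reproduces the 12-mutation construct and net energies", {
  cand <- read_candidate_table("table1_v3")
  expect_length(cand, 12)
  v3 <- design_construct(cand, name = "V3")
  expect_length(v3$mutations, 12)
  expect_equal(v3$net_energy_murine_context, -3.55)
  expect_equal(v3$net_energy_humanized_context, 4.61)
  # phenotype column reproduced row by row
  phen <- ifelse(vapply(v3$decisions, function(d) d$action, "") ==
                   "revert_to_murine", "Murine", "Human")
  expect_equal(phen, c("Murine", "Murine", "Murine", "Human", "Murine",
                       "Human", "Human", "Murine", "Murine", "Human",
                       "Murine", "Human"))
})

test_that("the V5 fixture reproduces the 9-mutation construct with ablations", {
  cand <- read_candidate_table("table2_v5")
  v5 <- design_construct(cand, epitope_ablations = v5_epitope_ablations(),
                         name = "V5")
  expect_length(v5$mutations, 9)
  expect_equal(v5$net_energy_murine_context, 1.62)
  expect_equal(v5$net_energy_humanized_context, 0.90)
  expect_true(all(v5$phenotype_per_mutation == "Human"))
  # the destabilizing CDR-H2 ablations are admitted by the bypass, not energy
  abl <- vapply(v5$decisions, function(d) d$rule_fired, "")
  expect_equal(sum(abl == "epitope ablation"), 4)
  # without the bypass the destabilizing ablations drop out
  v5b <- design_construct(cand, name = "V5-noablation")
  expect_lt(length(v5b$mutations), 9)
})

test_that("net energy sums exactly, permutation-invariantly, with table rounding", {
  cand <- read_candidate_table("table1_v3")
  expect_equal(net_mutation_energy(cand, "parental"), -3.55)
  expect_equal(net_mutation_energy(cand, "model"), 4.61)
  set.seed(3)
  expect_equal(net_mutation_energy(cand[sample(12)], "parental"), -3.55)
  expect_equal(net_mutation_energy(list(), "parental"), 0)
  one <- rec("HC:A1S", 0.10, 0.2, "humanizing")
  expect_equal(net_mutation_energy(list(one), "parental"), 0.10)
  # rounding convention: half away from zero at 2 decimals
  expect_equal(net_mutation_energy(list(rec("HC:A1S", 0.005, 0, "x")),
                                   "parental"), 0.01)
  expect_equal(net_mutation_energy(list(rec("HC:A1S", -0.005, 0, "x")),
                                   "parental"), -0.01)
})

test_that("empty candidate lists and duplicates behave per contract", {
  empty <- design_construct(list(), name = "none")
  expect_length(empty$mutations, 0)
  expect_equal(empty$net_energy_murine_context, 0)
  dup <- list(rec("HC:I20L", -0.5, -0.5, "humanizing"),
              rec("HC:I20V", -0.5, -0.5, "humanizing"))
  expect_error(design_construct(dup), "duplicate")
})

test_that("tightening the negligible threshold never adds humanizing mutations", {
  cand <- read_candidate_table("table1_v3")
  n_human <- function(thr) {
    d <- design_construct(cand, design_rules(negligible_threshold = thr))
    sum(d$phenotype_per_mutation == "Human")
  }
  counts <- vapply(c(1.0, 0.5, 0.3, 0.1, 0.005), n_human, numeric(1))
  expect_false(is.unsorted(rev(counts)))
})
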