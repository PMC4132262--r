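---
title: "Models and methods behind abrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abrefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`abrefine` covers two kinds of computation: a *design* side (structure-based
ΔΔG scanning, mutation-selection rules, humanness and epitope scoring) and
an *analysis* side (kinetic, thermal and cytotoxicity assay models).  This
vignette records the models, their assumptions, the tunable parameters, and
the design choices made where the design was genuinely open.  It states no
empirical result beyond what the package's tests compute.

## 1. The folding-energy function

`fold_energy()` evaluates five terms on a heavy-atom (united-atom)
structure; `mutation_energy()` reports their difference between folded and
unfolded states of mutant and wild type:

ΔΔG = [E_folded(mut) − E_unfolded(mut)] − [E_folded(wt) − E_unfolded(wt)],
positive = destabilizing.

| term | form | key parameters (defaults) |
|---|---|---|
| van der Waals | Lennard-Jones 6-12 over non-bonded heavy-atom pairs | element ε, r_min from `lj_params.csv`; cutoff 8 Å with CHARMM-style energy switching from 6 Å |
| electrostatics | Coulomb with distance-dependent dielectric ε(r) = 4r | partial charges from `charges.csv` (backbone dipoles, ±1 on charged side chains) |
| polar solvation | Still-style pairwise Generalized-Born, τ = 332.064·(1 − 1/80) | intrinsic radii from `gb_radii.csv`; coarse pairwise volume descreening (scale 0.8, Born radii capped at 25 Å) |
| nonpolar solvation | γ·SASA, Shrake–Rupley | γ = 0.0054 kcal/mol/Å², probe 1.4 Å, 960 fixed sphere points |
| side-chain entropy | per-residue table (−TΔS = 0.593·ln n_rot) | `rotamer_entropy.csv` |

The reported value is the weight-vector dot product of the five term
differences (`term_weights()`, all defaulting to 1), so weighted ΔΔG is
exactly linear in the weights — a property the tests assert at random
weight vectors.

Choices worth recording:

* **Exclusions.** All pairs within one residue are excluded, as are
  backbone/CB–backbone/CB pairs of sequence-adjacent residues.  This
  replaces an explicit bond graph; it slightly over-excludes 1-4 backbone
  interactions, which a toy force field tolerates, and makes an isolated
  alanine's vdW term exactly zero (a test case).
* **GB locality.** The off-diagonal GB pair terms share the non-bonded
  switching cutoff.  Mixing an 8 Å cutoff on Coulomb with an uncut GB sum
  would make distant mutations spuriously coupled through solvation
  screening; with the shared cutoff, the tested additivity of mutations
  more than 12 Å apart holds to well under 0.1 kcal/mol.
* **Unfolded reference.** An extended tripeptide (site ± 1, φ = −139,
  ψ = 135) rebuilt from sequence with the same energy terms.  The
  side-chain entropy term is counted for folded structures only: the
  unfolded chain's side chains are taken as unrestricted, which is what the
  table values mean.  Identity mutations (allowed only when explicitly
  flagged) return the input structure unchanged, so their ΔΔG is exactly 0
  by construction — the scanner's principal self-test.
* **Mutant building.** Backbone and O are never moved.  The side chain is
  regrown along the existing CA→CB vector (CB rebuilt from backbone
  geometry for glycine targets, torsion(C,N,CA,CB) = +122.5°) with χ angles
  from a coarse staggered rotamer library (`rotamers.csv`: χ1 ∈ {−60, 180,
  60}, χ2 ∈ {180, 65, −65}, χ3/χ4 trans, proline fixed), choosing the
  rotamer with the fewest steric clashes (distance < 0.8·Σ r_min) against
  the fixed environment; ties go to the lowest rotamer index.  No
  minimization — determinism is valued over accuracy.
* **Hydrogens and protonation** are not modeled; crystal structures lack
  hydrogens and no protonation protocol is assumed.

**What the scanner is not.** The original design work used a commercial
CHARMm-based pipeline.  This module is a deliberately simplified
re-implementation: its decision-relevant properties (sign conventions,
identity zero, additivity, weight linearity, deterministic rotamer choice)
are tested, but its absolute energies are not comparable to published
per-mutation values, and nothing in the package asserts such agreement.
The design engine therefore consumes the *published* candidate tables at
face value (bundled as `table1_v3.csv` / `table2_v5.csv`), and the scanner
provides the same record type for new structures.

## 2. Mutation-selection rules

The source narrative describes its criteria prose-style; `design_rules()`
is the minimal formal rule system consistent with every row of both
bundled tables:

* back mutation → accept if `ddg_parental < 0`, or
  `ddg_model < −0.5` kcal/mol, or the substitution involves Gly/Pro;
* humanizing mutation → accept if `ddg < 0.5` kcal/mol in *both* contexts
  (stabilizing or negligible);
* epitope-ablating mutations bypass the energy gate entirely (one bundled
  CDR-H2 ablation is +1.91/+1.80 kcal/mol and is included regardless).

Two reconstructions are flagged: the model-context clause exists solely to
admit a back mutation that is +0.17 in the parental context but −0.95 in
the model, and the humanizing predicate is applied per context rather than
as a two-clause disjunction (one accepted humanizing mutation is −0.64 in
the parental context and +0.01 in the model; any rule demanding
`|ddg_parental| < 0.5` or `ddg_model ≤ 0` would reject it).  Every
`design_construct()` decision records which clause fired so alternative
rule systems can be compared.  Net energies are exact sums reported to two
decimals, halves away from zero — the tables' printed convention.

## 3. Humanness and epitope scanning

`t20_score()` is the top-20 humanness metric: global Needleman–Wunsch
alignment (match +1, mismatch 0, affine gaps open −10 / extend −1; gap
parameters are declared defaults, not literature-recovered), identity =
100·matches/alignment-length *including gap columns* (configurable), score
= mean of the top min(20, |db|) identities.  The original tool's
similarity-search retrieval is replaced by an exhaustive scan — identical
result at desk scale.  Framework-only scoring splices CDR positions out of
the query.  Absolute scores are database-dependent, so the package ships a
generator (`make_human_v_db()`) rather than any real database; published
score tables are not reproduction targets.

`scan_epitopes()` scores every 15-mer window by its best 9-mer core (7
offsets, leftmost tie wins) against a 9×20 matrix.  The bundled toy matrix
rewards hydrophobic anchors at core positions 1/4/6/9; its thresholds
(high 6, moderate 3) are arbitrary config defaults, because the upstream
use is a binary flag ("moderate-affinity epitope present") and no allele
or percentile calibration is in scope.  `epitope_overlap()` uses the
half-open core interval [core_start, core_start + 9).

## 4. Assay models

**SPR.** The bivalent-analyte scheme with statistical factors 2·k_on (first
binding) and 2·k_off2 (second release) — the convention of instrument
evaluation software; the free-site signal is L = R_max − [AB] − [AB2].
Integration: `deSolve::lsoda`, rtol 1e-8, association and dissociation
solved as separate segments, output interpolated onto the requested grid.
With k_on2 = 0 the scheme reduces to 1:1 Langmuir with k_obs = 2·k_on·C +
k_off and plateau R_max·2k_onC/(2k_onC + k_off); `langmuir_closed_form()`
codes that solution independently and the simulator is tested against it to
0.5%.  (Note the factor 2 carries into the reduced model — a "Langmuir
plateau" written without it does not solve this ODE.)  `fit_bivalent()` is
a global fit across all curves on log-transformed parameters
(positivity by construction), initialized at k_on 1e5 M⁻¹s⁻¹, k_off 1e-3
s⁻¹, k_on2 1e-4, k_off2 1e-3, R_max = 1.1·max(response) — magnitudes of the
published rate-constant table.  Standard errors come from the Jacobian via
the delta method.  K_D = k_off/k_on, reported in nM to 3 significant
figures.  Mass transport and surface heterogeneity are out of scope.

**DSF.** `tm_derivative()` = smoothed central differences (moving average,
5-point default window) with parabolic vertex refinement; peaks above 10%
of the largest |dF/dT| are reported by descending height.  Vendor smoothing
is unpublished, so the window is exposed.  Fab-peak assignment uses an
expected-range filter (default 60–85 °C) plus `peak_rank`, never a guess.
`delta_tm()` uses the pooled-variance two-sample Student's t (two-tailed;
the stated test is Student's, not Welch's); replicate scatter is treated as
SD, consistent with the p-values the derivation reproduces (n = 3,
75.4 ± 0.5 vs 73.6 ± 0.3 → t = 5.35, df = 4, p ≈ 0.006).

**ADCC.** Specific lysis = 100·(sample − spontaneous)/(maximal −
spontaneous).  `fit_4pl()` fits y = bottom + (top − bottom)/(1 +
10^((log₁₀EC50 − log₁₀x)·hill)) with quartile-based starts.  The F test
shares *only* log₁₀EC50 between the two samples (bottom/top/hill stay
per-sample) — the shared fit is multi-started from both samples' EC50s and
their midpoint so the constrained optimum is found reliably.  F =
[(RSS_shared − RSS_sep)/(df_shared − df_sep)]/[RSS_sep/df_sep]; numerical
F < 0 is clipped to 0 (p = 1).  Relative potency = EC50_ref/EC50_test at
one decimal, halves away from zero.  Under the null (equal EC50, triplicate
curves, 3-percentage-point noise) the measured type-I error at α = 0.05 is
slightly above nominal (≈ 0.058 over 3000 trials) — ordinary
finite-sample behavior for extra-sum-of-squares tests on nonlinear fits —
and the suite checks it stays within [0.03, 0.07] over 500 trials seeded
from one master stream (consecutive-integer seeding of a Mersenne–Twister
produces correlated streams and is avoided).

## 5. Synthetic data: what it does and does not show

All generators are pure functions of (config, seed): they save and restore
the global RNG state, and equal seeds give bit-identical output.

* `make_toy_fab()` builds a 2-chain × 60-residue four-helix mini-domain
  with an engineered hydrophobic core (Leu/Val inward, polar cycle
  outward), side chains packed by the scanner's own minimum-clash rule, and
  0.02 Å seeded jitter to break symmetry.  It exists to give the scanner
  buried and exposed sites with complete backbones; it is *not* an
  antibody fold, and no structural conclusion about real Fabs follows from
  tests on it.
* `make_human_v_db()` mutates bundled germline-like heavy/light templates
  (synthetic stand-ins styled after common human framework families) with
  per-position substitution probability ≤ 0.3.  It reproduces the
  *mechanics* of humanness scoring, not the composition of any real
  repertoire.
* `make_assay_bundle()` generates the three assay data sets under stated
  true parameters: six sensorgrams at 50–1600 nM twofold (120 s
  association, 300 s dissociation, 1.5 s sampling), triplicate melt curves
  on a 25–99 °C grid (0.5 °C steps; default transitions at 73.6 °C and
  82 °C emulating Fab and Fc), and triplicate 4PL lysis tables over eight
  half-log concentrations spanning the EC50.  Noise is Gaussian
  throughout — adequate for parameter-recovery testing, silent about
  heavier-tailed instrument artifacts, drift, or regeneration effects.

Passing recovery tests on these generators demonstrates that the fitters
invert their own forward models at realistic noise; they do not certify
performance on real instrument exports, which carry systematic deviations
the noise model does not emulate.

## 6. Problem sizes and numerical conventions

The suite runs at desk scale by choice: a ~1700-atom toy structure (full
identity-mutation sweeps take seconds with the compiled kernels), a
200-sequence humanness database against a brute-force oracle, 20-seed
kinetic recovery studies, a 10-case Tm sweep, and a 500-trial F-test
calibration.  Printed-value conventions follow the field's tables: energies
to 2 decimals, ΔTm and potency ratios to 1 decimal (halves away from zero,
`round_half_away()`), K_D to 3 significant figures.  Mutation positions are
1-based indices into the mature V-region — no Kabat/IMGT renumbering;
region labels are annotations supplied with the sequence.  PDB chain ids
map to HC/LC only through an explicit `chain_map`, never by guessing;
altloc resolution takes the highest occupancy, ties to the first record.

## 7. Known limitations

* The energy model's absolute scale is arbitrary (tripeptide reference +
  toy parameters); only differences, signs and invariants are meaningful.
* Proline's ring is approximated by fixed χ values and aromatic ring
  closure is near-ideal rather than exact; geometry is plausible, not
  refined.
* The bivalent fitter assumes a shared R_max across the dilution series and
  no analyte depletion.
* The humanness monotonicity property (adding database sequences never
  lowers the score) holds only once the database reaches the top-k size
  (k = 20): below that, the top-min(20, n) mean can decrease when a poor
  match joins — a property of the definition, exercised in tests at
  n ≥ 20.
* `fit_4pl()` refuses EC50 estimates far outside the tested concentration
  range instead of extrapolating; truly flat curves are reported as
  unidentifiable rather than fitted.
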