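---
title: "Models and methods behind mabpliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mabpliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabpliers)
```

`mabpliers` analyses the mechanism by which a bivalent IgG can inhibit
tetrameric β-tryptase: four Fabs occupy four exosites (one per protomer),
and a single IgG bridging two diagonally opposed protomers strains its
upper hinge and pries the ring apart. This vignette documents the models,
their assumptions, the tunable parameters, the synthetic-data generators
the tests run on, and the numerical choices made where the design was
genuinely open.

## 1. The hinge-wingspan ("molecular pliers") model

### Model

The two Fab heavy-chain C-termini of a bridging IgG must span a fixed
anchor distance `d_req` across the tetramer diagonal (51 Å in the
crystal structure of the Fab-decorated tetramer). One upper hinge of
`n` residues contributes

* relaxed span: `L_ref · n / n_ref` Å (default 21 Å for the reference
  10-residue IgG1 upper hinge, i.e. **2.1 Å per residue**),
* tense (fully elongated) span: `f_tense` times that (default 1.5,
  from ~3 Å vs ~2 Å per residue in elongated vs relaxed linkers).

Both hinges act in series, so two-hinge spans are twice the one-arm
values: 42 Å relaxed and 63 Å tense at `n = 10`. Classification of an
unconstrained IgG1-scaffold hinge:

| condition | class / reason |
|---|---|
| inter-hinge disulfide (IgG2-like, engineered Cys) | `none / constrained` |
| `tense_both + ε < d_req` | `none / no_reach` |
| `relaxed_both > d_req + ε` | `none / no_strain` |
| `|d_req − relaxed_both| ≤ ε` | `partial / marginal_strain` |
| otherwise | `full / strained_ok` |

The strain ratio `(d_req − relaxed_both)/(tense_both − relaxed_both)`
locates the anchor distance within the relaxed–tense bracket; it is
reported only when `d_req` actually falls inside that bracket, since
outside it the quantity loses its interpretation as a fractional
elongation.

### Parameter choices

* `L_ref = 21` Å / `n_ref = 10`. We anchor the per-residue span on the
  21 Å figure for the 10-residue reference hinge (2.1 Å/residue) rather
  than the looser "~2 Å per residue" prose value, because 21 Å is the
  quantitative anchor from which the 42 Å and 63 Å spans derive. The
  2.1 Å reading also reconciles the quoted ~17–26 Å window with the
  8–12 residue window (8·2.1 = 16.8, 12·2.1 = 25.2), which a strict
  2.0 Å rule (16–24 Å) does not. `L_ref = 20` remains selectable.
* `ε = 1.0` Å. The tolerance that lets the 8-residue hinge
  (tense span 50.4 Å) still reach the 51 Å anchors, reproducing the
  8–12 window; it also defines the `partial` band, which with defaults
  contains exactly `n = 12` — matching the one experimentally partial
  variant (+GG). Whether "partial" should instead be a strain-ratio
  threshold is not decidable from the available data; the ±ε band on the
  relaxed span is the simplest rule that reproduces the observations.
* Scope: the calibration is for the IgG1 scaffold. The IgG4 isotype
  (7-residue upper hinge) retains full activity experimentally, which a
  pure length model cannot explain — plausibly because its hinge
  geometry and Fab orientations differ. Rather than silently
  misclassify, `predict_inhibition()` returns class `NA` with reason
  `unsupported_scaffold` for unconstrained non-IgG1 scaffolds
  (`allow_cross_scaffold = TRUE` overrides). Constraint, in contrast,
  is scaffold-independent: a tethered hinge cannot strain, so IgG2 is
  classified `none/constrained`.
* Constraint detection: the explicit `constrained` column is
  authoritative (the experiments, not a computation, establish which
  hinges are tethered); `load_variants(infer_constraint = TRUE)` can
  additionally flag hinges with more cysteines than the scaffold
  baseline (one for IgG1).
* Residue counting strips alignment gap dashes, so the gapped panel
  strings ("EPKSCDKTH---------T") count the terminal residue after the
  gap run.

## 2. HDX-MS analysis

### Isotope envelopes and the binomial-mixture forward model

Natural envelopes are aggregated isotopic distributions over integer
mass-offset bins, computed by convolving per-element isotope patterns
raised to the peptide's elemental composition (residues + H₂O), truncated
at cumulative probability `1 − 10⁻⁶` and renormalised. Deuteration adds a
mass-shift distribution: a mixture of binomials
`Σⱼ wⱼ · Binom(N_ex, pⱼ)` convolved with the natural envelope. Exchange-
competent amides follow the standard fast-back-exchange convention
`N_ex = length − 2 − #(prolines at positions ≥ 3)` (the rule is
configurable; the source experiments do not state theirs).

### Fitting and F-test model selection

`fit_mixture()` minimises the residual sum of squares between the model
and the observed envelope. The single-population problem is solved by a
coarse grid (Δp = 0.025) plus golden-section refinement — effectively a
global optimum, verified in the tests against a 10⁻⁴-resolution grid
search. Multi-population fits use box-constrained `nlminb` over
`(p, stick-breaking weights)` from a deterministic start set (sorted
combinations of a coarse p-grid plus a split of the one-population
optimum; 16 starts by default). Populations are reported sorted by `p`.

`select_populations()` compares n against n+1 populations with the
nested-model F statistic
`F = ((RSS_n − RSS_{n+1})/(df_n − df_{n+1})) / (RSS_{n+1}/df_{n+1})`,
`df = bins − (2·n_pop − 1)`, accepting the larger model at
`α = 0.05` by default. The exact degrees-of-freedom bookkeeping of the
original in-house implementation is not public; the standard nested
F-test is substituted. Two guards: a smaller model that already fits to
machine precision is kept (otherwise noiseless data would always escalate),
and a larger model with exactly zero residual is accepted outright.
Monte-Carlo calibration (1000 unimodal replicates, Gaussian intensity
noise σ = 0.003) gives a type-I error of ~0.02–0.04 — slightly
conservative, as expected when the extra parameters live partly on the
boundary of the constraint box.

### Uptake, back-exchange, and the differential criterion

Uptake from a fit is `N_ex · Σ wⱼ pⱼ` Da; back-exchange correction
divides by the fractional recovery `r` (default 0.85, the expected
average recovery of a cold quench/LC workup), capping at `N_ex` with a
warning. The differential criterion deliberately mirrors laboratory
practice for duplicate designs: a peptide is differentially protected
when at any labeling timepoint the absolute difference of state means
exceeds the sum of the duplicate ranges of both states. The criterion is
applied to uncorrected uptake values by default — the recovery factor is
a shared scale and cancels from the comparison.

### Intrinsic rates and empirical protection factors

Intrinsic rates use the standard poly-DL-alanine reference constants in
D₂O at 20 °C (log₁₀ k_A = 1.62 M⁻¹min⁻¹, log₁₀ k_B = 10.05 M⁻¹min⁻¹,
log₁₀ k_W = −1.5 min⁻¹, pK_D = 15.05) with nearest-neighbor side-chain
corrections, N-/C-terminal corrections, first-order pD dependence and
Arrhenius temperature scaling (E_a = 14/17/19 kcal·mol⁻¹ for
acid/base/water catalysis). First two residues and prolines are excluded.
At pD 7 and 20 °C an interior alanine exchanges at ~100 min⁻¹, and a one-
unit pD increase scales rates tenfold (base-catalysed regime) — both
properties are asserted in the tests.

The empirical protection-factor estimator fits a *single* PF per
peptide/state, `D(t) = Σᵢ (1 − exp(−k_int,i · t / PF))`, by least squares
on log₁₀ PF. This is a deliberate simplification of a fuller Bayesian
treatment whose details are not available; its intent — a PF point
estimate with an uncertainty — is honoured by propagating the replicate
spread through the fit's local sensitivity:
`σ_PF = s / sqrt(Σₜ (∂D/∂PF)²)` with `s` the half-range-based replicate
scale. Curves with no measurable uptake return the upper search bound
(10⁸) flagged `no_uptake`; non-monotone mean curves beyond twice the
pooled replicate range are flagged.

### Residue-level consolidation

A residue is reported protected when it is covered by at least one
significant peptide and not covered by any non-significant peptide (set
subtraction): overlapping non-significant peptides "explain away" the
flanks of long significant peptides. Resolution is therefore set by the
peptide overlap structure, which is why the generator defaults to a
dense tiling (below).

## 3. Structure operations

* **Contacts**: any-heavy-atom distance ≤ 4.0 Å between residues of two
  chain groups, the cutoff conventionally used for epitope/paratope
  definition. The cell-list accelerated path is required (and tested) to
  agree exactly with brute-force all-pairs.
* **SASA**: Shrake–Rupley with a deterministic golden-spiral point set
  (960 points/atom by default; halving changes totals by <1 %), probe
  1.4 Å, standard van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å,
  overridable). A lone atom recovers the analytic sphere area to
  quadrature exactness since every point is accessible.
* **Interface area**: the headline buried surface area is the half-sum
  convention `(ΔSASA_A + ΔSASA_B)/2`; per-side totals and per-chain
  shares (e.g. heavy- vs light-chain contribution) are also reported
  because conventions differ between laboratories. Because the point set
  is fixed in the global frame, SASA is rotation-invariant only to
  quadrature accuracy (~1 %); the tests allow 2 %.
* **Kabsch RMSD**: optimal proper rotation via SVD with the determinant
  sign correction; cross-checked in the tests against bio3d's
  independent superposition.
* Residue numbering is taken verbatim from the input file (the field
  uses chymotrypsinogen numbering for tryptase and Kabat numbering for
  Fabs); no renumbering is attempted.

The deposited crystal structure of the Fab-decorated tetramer would
allow the published interface numbers (682 Å² BSA, ~71 % heavy-chain
share, 51 Å anchor spacing, 4 bound Fabs) to be recomputed directly with
these operations; since the package's tests are self-contained and
offline, those checks run instead against the toy complex whose geometry
is known by construction.

## 4. Binding and inhibition

* **Velocity**: least-squares slope over a configurable linear window;
  traces with strong curvature (quadratic component >10 % of the signal
  range) are flagged rather than silently fitted.
* **4PL**: `y = bottom + (top − bottom)/(1 + (x/IC50)^h)`, fitted by
  Levenberg–Marquardt on log₁₀ IC50 with data-driven starts. The
  midpoint identity (response at IC50 = (top+bottom)/2) is exact in the
  parameterisation.
* **Bell (hook) model**: the product of a falling and a rising logistic,
  chosen for parsimony — the phenomenon is named, not modelled, in the
  source literature. The reported IC50 is the falling-phase midpoint.
  Model selection against the plain 4PL uses corrected AIC; on
  synthetic hook data the bell model wins decisively, and on plain 4PL
  data it does not.
* **1:1 Langmuir**: global fit across the dilution series of
  `R(t) = R_max·C/(C+K_D)·(1 − e^{−(k_on C + k_off)t})` (association)
  and exponential decay from the end-of-association response
  (dissociation), on log-scaled rate constants. `K_D = k_off/k_on` holds
  identically because K_D is derived, never fitted independently.
* **Avidity simulator** (exploratory, qualitative only): equilibrium
  configuration model of 4 sites as two bridgeable diagonal pairs.
  Per-pair weights: monovalent occupancy `a = 2·K_a·F` per site (two
  arms per IgG) and bridged state `b = a·β`, where the dimensionless
  enhancement `β = K_a·C_eff` (default 100) encodes the effective local
  concentration of the tethered second arm. Free IgG `F` is solved by
  `uniroot` to relative mass-conservation error ≤ 10⁻⁹. The bivalent
  fraction rises then falls with total IgG — monovalent weights grow as
  F², bridged only as F — reproducing the hook effect qualitatively.
  The simulator is never used for quantitative claims; whether the
  experimental hook is purely avidity-statistical cannot be adjudicated
  by this model.

## 5. Synthetic-data generators and what the tests show

All generators are seeded (Mersenne–Twister via `withr::with_seed`, so
the caller's RNG state is untouched) and serialise their ground truth.

* **Variant panel**: the fifteen hinge sequences with constraint flags,
  scaffolds, affinity labels (~0.3–0.7 nM, all variants bind equally —
  the panel separates binding from inhibition) and observed outcomes.
  The affinity and outcome labels are fixture annotations, not computed
  quantities.
* **HDX datasets**: a proline-sparse synthetic 120-residue protein,
  10-residue peptides tiled every 3 residues (dense overlap, mirroring
  the deliberate maximisation of overlapping peptides in the real
  workflow and setting the consolidation resolution to ~2 residues),
  the six standard labeling times (0.5–1000 min) in duplicate, baseline
  PF 50 everywhere and 50-fold extra protection on residues 70–80 in
  the bound state. Duplicate noise is a systematic run offset
  (0.05 Da on the second replicate, shared across peptides and states)
  plus i.i.d. Gaussian noise (0.01 Da). The offset matters: the
  significance criterion compares mean differences against duplicate
  ranges, and with purely i.i.d. noise the ranges would be as random as
  the differences, giving a scale-invariant false-positive rate of
  several percent per timepoint. Run-level drift is also the realistic
  dominant component of HDX duplicate spread. Envelope intensities get
  additive Gaussian noise without clipping at zero, as in
  baseline-subtracted centroided spectra — clipping would bias
  near-zero bins upward and visibly inflate the F-test's type-I error.
* **Toy complex**: four protomer pseudo-chains (3×3×3 atom cubes) on a
  planar ring, four heavy/light pseudo-Fab pairs alternately above and
  below, one stem atom per Fab placed exactly 3.5 Å from its protomer
  (guaranteeing the 4 Å contact), and anchor atoms (residue 217, CA) on
  diagonal Fabs exactly `d` apart (default 51 Å) at ±12 Å height so
  diagonal and adjacent anchor distances differ. It is geometric, not
  physical: no sequence realism, no packing realism.
* **Curves**: 4PL (default IC50 4 nM — the scale anchor of the
  biochemical assay), bell (hook near 0.2 µM), and sensorgrams
  (k_on 2·10⁶ M⁻¹s⁻¹, k_off 10⁻³ s⁻¹, K_D 0.5 nM, threefold dilutions
  from 100 nM, 3 min association / 10 min dissociation). Dose-response
  generators default to three replicates, mirroring triplicate
  independent experiments.

Passing tests on these fixtures demonstrate that the *algorithms* are
correct under their stated noise models — envelope deconvolution
recovers known mixtures, the F-test is calibrated, the differential
criterion localises known protection exactly, curve fits recover known
parameters. They do not demonstrate robustness to the pathologies of
real data: chromatographic carryover, peptide misidentification, EX1/EX2
mixtures beyond two populations, heteroscedastic detector noise,
refractive-index artefacts in SPR, or real protein packing in the
structural operations.

## 6. Problem sizes and runtimes

The stochastic checks use 1000 unimodal replicates (type-I error),
200 bimodal replicates (selection power), 38-peptide HDX datasets, a
332-atom toy complex, 30-point dose-response designs and ~2300-point
sensorgram series — sizes chosen so the full suite and the acceptance
script each complete in well under a minute on one CPU while keeping
Monte-Carlo error small relative to the tolerances tested.

## 7. Known limitations

* The hinge model is one-dimensional: no elastic energetics, no Fc
  geometry, no prediction of partial-inhibition magnitudes, no IgG4
  explanation.
* The pipeline starts downstream of peptide identification; raw
  spectra, retention-time alignment and charge-state deconvolution
  (beyond summing degenerate charge states) are out of scope.
* Nearest-neighbor rate corrections use the standard reference
  compilation; side-chain ionisation states are fixed at their neutral-pD
  defaults.
* The single-PF model collapses genuinely multi-exponential peptides
  into one effective parameter; its σ reflects replicate spread, not
  model misspecification.
* SASA rotation invariance is limited by quadrature (<1 % at default
  sampling); interface areas inherit that.
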