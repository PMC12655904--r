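---
title: "Methods: QSPR/QSAR modelling of PFAS-estrogen receptor binding"
author: "pfasER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSPR/QSAR modelling of PFAS-estrogen receptor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasER)
```

`pfasER` packages an in-silico screening workflow for per- and
polyfluoroalkyl substances (PFAS) against the estrogen receptors ERα and
ERβ: docking-derived affinities, multiple-linear-regression QSPR models on
physicochemical descriptors, applicability-domain and effect-profile
diagnostics, and the validation machinery around them. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Affinity scales and the docking-score conversion

The working affinity unit is pIC50 = −log₁₀(IC50 × 10⁻⁹) with IC50 in nM:
1 nM is pIC50 9, 100,000 nM (the decoy standardization floor) is pIC50 4.
Docking scores ΔG in kcal/mol are mapped to affinities by treating the score
as a binding free energy and the implied dissociation constant as the IC50:

IC50 (M) = exp(ΔG / RT),  R = 1.987 × 10⁻³ kcal mol⁻¹ K⁻¹.

The default temperature is 300 K (`temperatureK` is exposed on every entry
point). At that temperature the conversion reproduces the packaged ERα
reference panel (`loadFixture("table1_era_ligands")`) to within 0.4% — e.g.
−9 kcal/mol → `r round(scoreToIc50(-9), 1)` nM against the tabulated 278.38.
Two caveats are deliberate and documented rather than hidden: equating a
thermodynamic dissociation constant with an IC50 is an assumption, not a
pharmacological identity; and the ERβ panel (`table2_erb_ligands`) is *not*
consistent with any single temperature under this law — only its estradiol
row reproduces at 300 K — so no ERβ conversion value is treated as a
reference point. Validation against experiment reports the mean, sample SD
(n−1 denominator) and standard error SD/√n of predicted-minus-literature
pIC50 differences; on the packaged panels these SEs are
`r round(validateAgainstExperiment(loadFixture("table1_era_ligands")$ic50_nM,
loadFixture("table1_era_ligands")$predicted_ic50_nM)@standardError, 2)` (ERα)
and
`r round(validateAgainstExperiment(loadFixture("table2_erb_ligands")$ic50_nM,
loadFixture("table2_erb_ligands")$predicted_ic50_nM)@standardError, 2)` (ERβ).
Where a printed per-ligand pIC50 disagrees with the printed IC50 it derives
from (two rows of the ERα panel), the package recomputes everything from the
IC50 columns, which are internally consistent with the difference column.

## Descriptor tables and VIF elimination

A `DescriptorTable` is a ligands × descriptors numeric matrix with ligand
ids and per-descriptor metadata. The canonical set
(`canonicalDescriptors()`) has 11 members spanning bulk (average mass,
density), hydrogen bonding (donor/acceptor counts), flexibility (freely
rotating bonds), hydrophobicity (LogD at pH 7.4, surface tension), polarity
(polar surface area) and electronic structure (HOMO, LUMO, maximum positive
Fukui index). The historical reduction of a larger descriptor pool to these
11 was expert curation plus VIF elimination; the curated casualties are
recorded as a fixture list (`curatedExclusions()`), not re-derived.

Cleaning removes any ligand with a missing cell — no imputation, order
preserved, survivors untouched. VIF_j = 1/(1 − R²_j) regresses descriptor j
on the others with intercept; exact collinearity reports `Inf`. Iterative
elimination removes the max-VIF descriptor (ties broken by column order,
since no principled tie-break exists) until all VIF fall below the
threshold. The threshold defaults to 5; a verify-only mode reports
violations without removal, covering workflows that only audit an already
chosen descriptor set against a looser bound (such as 10). A substitution
map redirects removals: if the max-VIF descriptor is a key, its mapped
partner is removed instead — the mechanism by which LogD (physiologically
meaningful at pH 7.4 because it includes ionization) survives at the expense
of LogP. If the mapped partner is already gone, the max-VIF descriptor
itself is removed. Whether elimination should be rerun per dataset or a
single descriptor set reused across related datasets is left to the user;
both modes are trivially available because elimination is a pure function of
the table it is given.

## The MLR models

`fitQspr()` is ordinary least squares with intercept, requiring n > M + 1
and a full-rank design (rank deficiency errors and names the dependent
columns). The fitted object keeps the residual SD s = √(RSS/(n−M−1)), the
training leverages and (X'X)⁻¹, so applicability-domain diagnostics need no
refitting. Conventions for degenerate cases: a constant response yields zero
coefficients, the constant as intercept, and training R² reported as 0; in
`evaluateFit()` a zero-variance target makes R² undefined and it is reported
as `NA`, never 1. Q² = 1 − PRESS/SS_tot uses the exact leverage shortcut
PRESS = Σ (eᵢ/(1−hᵢ))², algebraically identical to leave-one-out refitting
(and tested against it); leave-one-out is used because the upstream
modelling tools never disclose their internal CV scheme, and LOO is the
conservative, deterministic default at these sample sizes.

Normalized coefficients follow the convention normalized = raw × sd(x),
expressing each coefficient as pIC50 change per descriptor SD; an optional
÷ sd(y) variant gives fully standardized betas, and both are labelled
explicitly in the model metadata because the two conventions are routinely
conflated in the QSPR literature. The four published reference equations
ship as fixtures at 4-decimal coefficient precision with intercepts 8.03,
8.02, 5.95 and 6.02; their published normalized coefficients imply the
descriptor SDs of the originating datasets (stored on the fixture models).
Two of the published training R² values (0.586, 0.480) depend on
supplementary descriptor spreadsheets that are not packaged; they are
reference metadata only, not reproduction targets. Splits follow either the
QSPR convention (a single random test ligand, focusing the analysis on
coefficients) or the QSAR convention (random 80/20), with the seed recorded
in the model metadata.

## Applicability domain

Williams-plot diagnostics: leverages are the hat-matrix diagonal for
training ligands and the quadratic form x'(X'X)⁻¹x under the training
projection for queries (no refit — the standard practice for external
points). Standardized residuals divide by the training residual SD; the
internally studentized variant (additional ÷ √(1−h)) sits behind a flag.
The critical leverage is h\* = 3(M+1)/N computed from the *actual* training
set supplied — never hard-coded, because the same study may legitimately use
N = 55, 68 or an 80% split depending on stage. Classification uses strict
inequalities (|r| > 3, h > h\*), so boundary points are in-domain, matching
the "acceptable fit means |residual| less than three" reading. The residual
scale s must be positive: a numerically perfect fit (s < 10⁻⁸ pIC50 units)
raises an error rather than dividing by ~0.

## Accumulated local effects

`aleCurve()` is standard first-order ALE: quantile edges over the observed
range (`gridSize = 20` intervals by default, matching common practice for
these models; uniform edges behind a flag), per-interval mean prediction
change from moving in-interval observations between the interval edges,
accumulation, then centering by the observation-weighted mean so curves read
as deviations from the average prediction. Empty intervals contribute zero
local effect and carry the accumulation forward. Both the centered span and
the raw accumulated range are reported, since summaries in the field
sometimes skip centering. For a purely additive linear model the curve is
exactly linear with the model's slope — the closed form the tests use — and
the span equals |coefficient| × observed range, which is why span rankings
follow |coefficient| when descriptor spreads are common. Note a tension
inherited from the source material: the published narrative names freely
rotating bonds and density as the dominant top-binder effects, but the
published normalized coefficients put average mass far ahead of density;
the package reports what the arithmetic gives.

## Validation machinery

**Pairwise ensembles.** `enumeratePairSplits()` builds one plan per
unordered pair of experimental compounds — C(12,2) = 66 plans for 12 — each
with the pair plus `nPoolTest = 5` pool compounds (sampled without
replacement, fresh per plan, from one master seed) as the test set and the
remaining experimental compounds plus `nPoolTrain` pool compounds as
training. Fixed exclusions are honored everywhere. `runEnsemble()` fits one
OLS model per plan and averages train R², test R² and Q².

**Large-set refinement.** `scoreCutoffFilter()` retains score ≤ cutoff
(inclusive; the boundary convention is a choice, stated, since "cutoff of
−7.0" does not specify strictness). `iterativeOutlierRefinement()` ranks all
current compounds by |residual| (training residuals from the fit, test
residuals from prediction, pooled by default; train-only behind a flag),
removes the top fraction of the *current* count (floor arithmetic,
cumulative across rounds — "10% then 20%" removes 10 then 18 of an initial
100), re-splits 80/20 with a seed derived from the recorded split seed, and
refits. Re-splitting is the only reading that keeps the ratio exact after
removal; preserving the original membership is available as an option in
spirit by supplying the same seed. Removed sets are disjoint by
construction.

**Benchmark separation.** With actives and decoys labelled,
separation = min(active predictions) − max(decoy predictions) in pIC50 and
fold ratio = 10^separation. Decoys are standardized to IC50 = 100,000 nM
(pIC50 4.0), the conventional ">100,000 nM" floor. Actives whose affinity
is a Ki are passed through unchanged — an identity mapping flagged in the
output metadata, because no conversion formula is defensible without assay
details.

## The synthetic-data generator

`SyntheticSpec` draws descriptors from a multivariate normal (the minimal
structure that exercises MLR and VIF nontrivially — correlation is needed to
make elimination do something), builds true pIC50 from a linear model,
observes it under Gaussian noise, and produces docking scores by the exact
inverse of the affinity conversion, so conversion round-trips are testable
to machine precision. Determinism: the descriptor draw, the pIC50 noise and
the score noise use seeds `seed`, `seed + 1`, `seed + 2`, so identical specs
give bitwise-identical datasets.

The `pfasLikeSpec()` preset defines the default study conditions:

* **Truth**: the published top-binder ERα equation (11 coefficients,
  intercept 8.03), so parameter-recovery tests target real published values.
* **Descriptor space**: centered, common spread of SD 2 per descriptor.
  Working in centered scaled units is a deliberate choice: QSPR practice
  standardizes descriptor blocks anyway, and the alternative — spreads
  matching the SDs implied by the published raw/normalized coefficient
  pairs — is statistically degenerate for testing: the average-mass term
  alone would span ~49 pIC50 units (driving every R² to 0.9999+, so no
  optimism or refinement property could be observed) while the milli-scale
  normalized coefficients (maximum Fukui index, 0.0011) would be
  statistically invisible at any realistic n. The common SD-2 spread keeps
  the implied signal (SD ≈ 0.74 pIC50) and the default noise in a regime
  (R² ≈ 0.8) where fitting, cross-validation, domain diagnostics and
  refinement all behave nontrivially.
* **Correlation**: average mass ↔ polar surface area r = 0.8 (the intrinsic
  mass–size–polarizability link), with weaker ties among size, flexibility
  and hydrogen-bonding counts, and mild negative LogD links — enough to give
  VIF elimination and ALE's correlation-robustness something to act on.
  One consequence is documented openly: under this collinearity the polar
  surface area coefficient (0.0185, 0.8-correlated with the dominant mass
  term) is only ~1.7 SEs from zero at n = 500, so *sign* recovery of every
  coefficient is not reliably achievable on the correlated design. Recovery
  checks therefore use the same truth and spreads with identity correlation
  (a well-conditioned design where the weakest coefficient sits at ~3.4
  SEs), while the correlated preset drives the collinearity-sensitive
  checks. This was decided from a power analysis of the designs.
* **Noise**: 0.35 pIC50 units, the scale of the published training RMSE.
* **Temperature**: 300 K for the score inversion.

What the generator does **not** emulate: real PFAS chemistry (no
fluorination patterns, no SMILES), non-Gaussian descriptor marginals
(counts are generated as continuous), heteroscedastic or structure-dependent
docking error, and assay-to-assay heterogeneity in experimental IC50s.
Passing tests therefore demonstrate the *statistical machinery* is correct
and well-calibrated under known ground truth — not that the published
equations generalize to new PFAS.

Toy complexes (`generateComplex()`) place a 3-atom ligand at the origin and
3-atom residues on spheres: designated contacts at radius cutoff − 0.5 Å,
all others at cutoff + 1.5 Å, so the contact set is provable (non-contacts
stay > cutoff + 0.5 Å from every ligand atom by construction). Cutoffs
≤ 1.5 Å are rejected as geometrically impossible for the cluster radii
used. Contact detection itself is all-atom, inclusive at the cutoff
(≤ 5.0 Å by default), counts residue instances by default (atom-pair and
per-complex-presence units are also available since the field's figures are
ambiguous about the unit), and is tested against an O(n²) brute-force scan
and under rigid rotation/translation.

## Problem sizes in the test suite

Monte-Carlo property tests use sizes chosen for statistical power: n = 500
for coefficient recovery (weakest well-conditioned coefficient ≈ 3.4 SEs),
n = 200 for contamination-refinement (at n = 100 the post-removal re-split
injects enough split randomness that the improvement rate sits exactly at
its acceptance boundary; at n = 200 it is stable at 98–99% across
independent seed ranges), 100-seed replicate loops for rates, and ≤ 200 × 12
random instances for oracle-agreement checks. These run in well under a
minute in total.

## Known limitations

* The thermodynamic score conversion is a modelling assumption; it is
  validated against one receptor panel and explicitly not against the other.
* Published-model fixtures carry 4-decimal coefficients and 2-decimal
  intercepts; evaluations against them inherit that printed precision.
* No regularized or nonlinear regression, no interaction (second-order)
  ALE, no Ki↔IC50 pharmacological correction, no docking execution, and no
  descriptor acquisition from structures — inputs are tables the user
  supplies or the generator makes.
* Confidence intervals for coefficients are reported by the tests via the
  standard OLS machinery; the package deliberately stops short of formal
  significance claims for the published equations, whose data are not
  packaged.
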