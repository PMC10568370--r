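---
title: "Methods: rebalancing measured fluxes and biomass stoichiometry in FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rebalancing measured fluxes and biomass stoichiometry in FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbarebalance)
```

## The model

A constraint-based metabolic model is a stoichiometric matrix
$N \in \mathbb{R}^{m \times n}$ over internal metabolites, flux bounds
$lb_i \le r_i \le ub_i$ in mmol/(gDW·h), optionally a general linear block
$A r \le b$, and a biomass pseudo-reaction whose flux is the growth rate
$\mu$ in 1/h. Flux balance analysis (FBA) maximizes a linear objective
(usually $\mu$) subject to the steady-state condition $N r = 0$ and the
bounds. Fixing measured rates $r_i = f_i$ for a set $F$ of reactions can
make this system infeasible; this package computes minimal corrections
that restore feasibility, in three independent adjustment classes.

**Flux corrections.** Each soft-measured rate gets a slack,
$r_i = f_i - \delta_i$; the QP formulation minimizes
$\sum_i w_i \delta_i^2$, the LP formulation splits
$\delta_i = \delta_i^+ - \delta_i^-$ with non-negative parts and minimizes
$\sum_i w_i(\delta_i^+ + \delta_i^-)$. The LP typically concentrates
corrections on few measurements, the QP spreads them; the guideline runs
both because the contrast is diagnostic.

**Biomass-component adjustment.** Each biomass component $k$ with signed
coefficient $c_k$ (consumed components negative, mmol/gDW) gets a slack
$\beta_k$ in its steady-state row:
$\sum_{j} n_{kj} r_j + (c_k + \beta_k)\mu = 0$. Because $\beta_k \mu$ is
bilinear, $\mu$ must be fixed — the growth measurement is always
hard-fixed whenever biomass or GAM adjustment is enabled, and requesting
these adjustments without a growth measurement is an error. Mass
conservation $\sum_k \beta_k \, MW_k = 0$ keeps the biomass at its nominal
1 g/gDW; molecular weights come from the metabolite formulas (or explicit
weights for pseudo-metabolites). Slacks are bounded,
$|\beta_k| \le \texttt{maxRelBeta}\,|c_k|$, so no component can be
eliminated or switch from consumed to produced.

**GAM adjustment.** The growth-associated maintenance is the ATP
hydrolysis block (ATP + H2O → ADP + Pi + H+) embedded in the biomass
reaction with magnitude $g$, read off as the biomass ADP coefficient
(ADP is produced there only by that hydrolysis). Each of the five GAM
metabolites decomposes as $c_k = c_{k,B} + c_{k,GAM}$ with
$|c_{k,GAM}| = g$, ATP and H2O negative, ADP, Pi, H+ positive. A single
normalized slack $\beta_{GAM} \in [-1, 1]$ moves all five together by
$\gamma\,\mathrm{sign}(c_{k,GAM})\,\beta_{GAM}$, where $\gamma \le g$ caps
the change; the adjusted demand is reported as
$g' = g + \gamma\,\beta_{GAM}$. GAM does not enter the mass-conservation
constraint because hydrolysis is elementally and mass balanced.

All enabled blocks share one objective (the merged problem); disabling a
block removes its variables entirely.

## Tunable parameters

| parameter | unit / range | default | rationale |
|---|---|---|---|
| `mode` | lp, qp | qp | QP spreads corrections by precision; LP is sparser but non-unique |
| `fluxWeightScheme` | — | `sd_reciprocal` | $w_i = 1/sd_i$: corrections cheaper where the assay is noisier; `sdSquared` gives the $1/sd_i^2$ variant |
| `fluxScale` | > 0 | 1 | all flux weights are divided by it; lowering it makes flux corrections more expensive relative to biomass changes (e.g. 0.01 reproduces a 100× priority on keeping fluxes) |
| `biomassWeightScheme` | — | `relative_molar` | $z_k = 1/c_k^2$ (QP) or $1/|c_k|$ (LP): minimizes relative molar changes; `relative_mass` uses $MW_k$ to penalize gram changes instead |
| `gamWeight` | ≥ 0 | 1 | weight on the normalized $\beta_{GAM}$ |
| `maxRelBeta` | (0, 1] | 0.3 | components may change by at most 30%; 1.0 is the loosest bound that preserves the component signs |
| `gamMaxChange` | mmol/gDW | ∞ (capped at g) | effective $\gamma = \min(g, \texttt{gamMaxChange})$ |

Entries with $sd = 0$ are treated as exact and hard-fixed (no slack);
an absent $sd$ under `sd_reciprocal` falls back to relative weighting for
that entry with a warning, and a measured value of exactly 0 under
relative weighting is likewise hard-fixed (its relative weight is
undefined, and a zero measurement is usually a deliberate "absent"
statement).

## Diagnostics before adjusting

`fvaPrecheck()` computes each measured reaction's feasible range under the
model constraints alone; measurements outside their range cannot be fixed
by any biomass change and call for bound revision first.
`elementalBalance()` sums, per element, the matter entering through the
measured exchanges minus the biomass drain $\mu \cdot$ content; gross
surpluses or shortages localize the inconsistency before any optimization.
`maxGrowth()` probes the achievable growth under subsets of the
measurements. `runGuideline()` packages the staged procedure — step 0
diagnostics, step 1 flux-only (LP and QP), step 2 biomass-side only
(GAM / components / both; these may legitimately be infeasible), step 3
merged — and flags corrected fluxes sitting on bounds, component changes
at their limit, and NGAM-like fixed demands (ATP-hydrolysis reactions with
a positive lower bound, which the workflow suggests converting into
adjustable measurements rather than silently rewriting).

## Solver layer

Both formulations reduce to one canonical form (variables with bounds,
equality block, inequality block, diagonal-quadratic or linear cost).

* **LP:** a dense bounded-variable two-phase revised simplex implemented
  in the package (no LP solver is among the package's dependencies
  otherwise). Row scaling to unit max-abs, bound-flip ratio test, Dantzig
  pricing with a Bland's-rule fallback against cycling, explicit
  infeasible/unbounded statuses. Problem sizes here (tens to a few hundred
  variables) are far below anything that requires sparse factorization.
* **QP:** the Goldfarb–Idnani dual method (`quadprog`). Three
  preprocessing steps make it robust on stoichiometric systems: variables
  pinned by singleton equality rows (hard-fixed rates) are substituted
  out; linearly dependent equality rows (conserved moieties) are removed
  by a QR rank screen, with an augmented-rank consistency check that
  reports genuine inconsistency as infeasibility; and fully determined
  systems (zero degrees of freedom, e.g. recovery problems with every flux
  fixed) are solved directly by linear algebra. Variables without a
  quadratic cost receive a $10^{-10}$ ridge, required for strict positive
  definiteness; the reported objective is always evaluated with the
  original weights.

The test suite cross-checks both backends against independent brute-force
oracles (vertex enumeration for LPs, active-set KKT enumeration for QPs)
on small networks, and against closed-form KKT solutions of two-variable
problems.

Numerical choices: constraint-feasibility tolerances are $10^{-9}$
(simplex) and $10^{-7}$ (QP presolve checks); mass conservation is
asserted to $10^{-8}$ relative in the tests; the "Unchanged" display
threshold in comparison tables is $5 \times 10^{-4}$ in the measurement's
units, matching the 2–3 decimals such tables print; raw values are always
retained in the JSON rendering. LP optima need not be unique, so
`optimumRange()` re-optimizes a named quantity (adjusted GAM, an adjusted
flux, a component coefficient) at the fixed optimal objective
(±$10^{-6}$ relative) and reports the interval; QP optima are unique in
the correction variables and collapse to a point.

## The synthetic generator

`makeToyModel()` builds fermentation-style networks: glucose and ammonium
uptake, homolactic catabolism (glc + 2 ADP + 2 Pi + 2 H+ → 2 lactate +
2 ATP + 2 H2O), one elementally balanced synthesis reaction per biomass
component drawn from a pool of real monomers (amino acids, a glycogen
unit), the full ATP/ADP/H2O/Pi/H+ cycle, and a biomass reaction whose
component coefficients are solved from seeded mass fractions so that
$-\sum c_k MW_k = 1$ g holds exactly, plus an embedded GAM of chosen size.
Every metabolite carries a real chemical formula, so the elemental
diagnostics run unmodified, and the ATP stoichiometry ties lactate
secretion to the maintenance demand, which makes GAM identifiable from
exchange measurements. Measurement noise is independent zero-mean
Gaussian per reaction with stated sds and a fixed seed (triplicate-style
reporting; no covariance structure is emulated).

What the toys deliberately do not emulate: genome-scale redundancy
(thousands of reactions with many alternate pathways), cofactor diversity
beyond the adenylate pool, compartments, and charge states. Passing tests
on these models demonstrates the correctness of the formulations and
solvers — not that a particular organism's GAM is wrong; on real models
the degrees of freedom are larger and conclusions need the full
diagnostic workflow. Problem sizes in the tests and the acceptance script
(networks of ~11–15 reactions, batches of 15–100 seeded instances) keep
the whole validation in the tens of seconds while still exercising every
code path; they are comfortably representative because the algorithms'
behavior does not change qualitatively with size at this scale.

## Design decisions

* **Sign conventions.** Consumed species carry negative coefficients
  throughout (SBML convention); uptakes are negative exchange fluxes. The
  CLI offers `--uptake-positive` for measurement tables printed in
  uptake-positive convention. H2O in the GAM block is treated as consumed,
  as the hydrolysis stoichiometry dictates.
* **GAM detection.** The five GAM metabolites are found by conventional
  id stems (atp/adp/h2o/pi/h, optionally compartment-suffixed) in the
  biomass reaction's dominant compartment, overridable per scenario file —
  BiGG-style ids dominate public models but must not be hard-wired. If ADP
  cannot be resolved and no explicit $g$ is given, GAM handling errors out
  rather than guessing.
* **Pure GAM carriers** (metabolites whose biomass-synthesis part
  $c_{k,B}$ is zero after the split) are excluded from the adjustable
  component set: a relative weight $1/c_{k,B}$ would be undefined, and
  their adjustment is exactly what $\beta_{GAM}$ represents.
* **Growth is never softened alongside biomass slacks.** Allowing a
  simultaneous growth correction would reintroduce the bilinearity that
  fixing $\mu$ removes.
* **Mass-check tolerance** defaults to $5\times10^{-3}$ g: published
  biomass reactions rarely sum to exactly 1 g and a hard error would
  block legitimate models; the check warns instead.
* **Lumping.** `lumpBiomass()` rewrites the biomass over macromolecule
  pseudo-metabolites (protein, RNA, …): each class enters with coefficient
  −1 and is produced by one synthesis reaction carrying the original
  component stoichiometry, which fixes the pseudo-metabolite's molecular
  weight to the class's grams per gDW; per-class maintenance ATP moves
  from the biomass GAM into the synthesis reactions. The rewrite preserves
  total mass and the producible growth exactly, and it turns
  "30% less phospholipid"-style statements into single-coefficient
  adjustments.
* **SBML subset.** Reading/writing covers SBML L3 + FBC v2 as used by
  curated models (species formulas, parameter-referenced bounds, active
  objective, boundary species). General linear constraints have no SBML
  representation and live only in scenarios/objects; FBC v3 and COBRA
  JSON/MAT dialects are out of scope. Explicit molecular weights of
  pseudo-metabolites are carried in species notes so lumped models
  round-trip.
* **Infeasibility is a result.** Step-2 scenarios are reported as
  infeasible rather than retried with loosened settings; the guideline's
  value is exactly this contrast. The LP/QP comparison is likewise
  presented without ranking — choosing the "most plausible" correction is
  left to the user.

## Known limitations

Elemental balances ignore charge; models with formula-less metabolites
lose the elemental diagnostics (with a clear error naming the metabolite).
The dense solver layer targets core-scale models: genome-scale models can
be read and FBA'd, but FVA over thousands of reactions would be slow.
The biomass adjustment introduces as many slacks as there are components,
so on under-constrained scenarios the component-level result is one of
many optima — use `optimumRange()` and, where available, additional
measurements (elemental composition, tracer-derived fluxes) to narrow it.
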