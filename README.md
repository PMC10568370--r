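# fbarebalance

Restoring feasibility of flux balance analysis (FBA) problems that break
when measured fluxes are fixed — by minimally adjusting the measurements,
the biomass reaction stoichiometry, and the growth-associated maintenance
(GAM) ATP demand.

## The problem

Constraint-based metabolic models describe a metabolome at steady state,
`N r = 0`, with flux bounds `lb ≤ r ≤ ub` and optional general linear
constraints `A r ≤ b`. Integrating experimental data means fixing measured
rates, `r_i = f_i` for `i ∈ F` (substrate uptakes, product excretions, the
growth rate μ). Measurement noise, modeling inaccuracies, or a biomass
reaction that does not match the growth condition routinely make the
resulting linear program infeasible. The biomass reaction is a particular
suspect: its stoichiometric coefficients `c_k` (mmol per gram dry weight)
are rough averages, and the GAM demand embedded in it — `g` mmol ATP
hydrolyzed per gDW (ATP + H2O → ADP + Pi + H+) — varies strongly between
estimates and growth conditions.

This package restores feasibility with minimal, weighted corrections in up
to three places, in linear (LP) and quadratic (QP) formulations:

1. **Measured fluxes** — slack variables `δ_i` with `r_i = f_i − δ_i`,
   minimizing `Σ w_i δ_i²` (QP) or `Σ w_i (δ_i⁺ + δ_i⁻)` (LP).
2. **Biomass composition** — slacks `β_k` on the component coefficients,
   `Σ_j n_kj r_j + (c_k + β_k) μ = 0`, under mass conservation
   `Σ β_k MW_k = 0` so the biomass still weighs 1 g/gDW, with
   `|β_k| ≤ maxRelBeta · |c_k|`. Requires μ fixed (the constraint is
   bilinear otherwise).
3. **GAM** — a single normalized slack `βGAM ∈ [−1, 1]` moving all five
   GAM metabolites together by `γ · sign(c_k,GAM) · βGAM`, reporting the
   adjusted demand `g′ = g + γ βGAM`.

Around the core sit the diagnostics a practitioner needs first: elemental
balances over the measured rates, flux-variability (FVA) pre-checks,
constrained maximum-growth probes, biomass introspection (1-g mass check,
GAM detection and extraction, lumping of components into macromolecule
pseudo-metabolites), and a staged guideline that runs and compares the
adjustment scenarios.

## Worked example

Every run below is fully reproducible; the numbers are the package's
actual output. We simulate an organism whose true GAM is 6 mmol/gDW, but
analyse its measurements with a curated model that assumes GAM = 12 — the
classic situation of a maintenance estimate carried over from a different
growth condition:

```r
library(fbarebalance)

organism <- makeToyModel(nComponents = 3, gam = 6,  seed = 11)  # generates the data
model    <- makeToyModel(nComponents = 3, gam = 12, seed = 11)  # what we analyse

meas <- simulateMeasurements(organism,
  sdProfile = c(EX_glc = 0.05, EX_lac = 0.1, BIOMASS = 0.005),
  noiseSeed = 2, include = c("EX_glc", "EX_lac", "BIOMASS"))
comparison <- runGuideline(model, meas)
comparison
#> ScenarioComparison: 6 scenarios
#>   step1_lp   flux corrections only (LP)               OV 43.8106
#>   step1_qp   flux corrections only (QP)               OV 21.2343
#>   step2a     GAM adjustment only                      infeasible
#>   step2b     biomass component adjustment only        infeasible
#>   step2c     biomass component + GAM adjustment       infeasible
#>   step3      merged flux + biomass + GAM adjustment (QP) OV 0.33935
```

`renderComparison(comparison, "tsv")` prints the table behind this:

```
quantity  model_value  step1_lp  step1_qp  step3
EX_glc    -10.045      -10.000   -9.513    -10.000
EX_lac    10.741       12.358    11.756    10.721
BIOMASS   0.721        0.588     0.559     Fixed
GAM       12.000                           5.741
OV                     43.81     21.23     0.3394
```

Reading it the way the guideline intends:

* **Step 1** (flux corrections only) can only make the system feasible by
  slashing the growth rate from the measured 0.721/h to ≈0.56/h — the
  model's inflated GAM cannot sustain the observed growth on the observed
  substrate, so the data get bent instead.
* **Step 2** (biomass-side adjustments alone, growth fixed) is infeasible
  here: the noisy glucose measurement sits outside what the fixed
  measurement set permits, which no biomass change can fix. The step-0
  artifacts in `comparison@step0` (FVA table, elemental balance) show this
  before any solve.
* **Step 3** (merged) keeps the measurements essentially intact (OV 0.34
  vs 21.2) and instead reduces GAM from 12 to **5.74**, recovering the
  generating value 6 from noisy data. `applyResult(model, ...)` writes the
  adjusted coefficients back into the model.

The same machinery recovers deliberate perturbations exactly: perturb two
biomass coefficients mass-neutrally, fix a flux distribution of the
unperturbed model, and `recoverBiomassPerturbation()` returns
`β_k = −Δ_k` to solver precision.

A thin command-line wrapper ships in `inst/scripts/fba-rebalance`
(`check`, `balance`, `guideline`, `make-fixture` subcommands).

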