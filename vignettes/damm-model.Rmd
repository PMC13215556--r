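---
title: "A mass-balance model of digestion, absorption and colonic microbial metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-balance model of digestion, absorption and colonic microbial metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damm)
```

## Why chemical oxygen demand

Metabolizable energy — the share of ingested food energy actually available
to the host — is classically estimated with the Atwater factors (4, 4 and
9 kcal per gram of protein, carbohydrate and fat). Those factors treat the
whole digestive tract as a black box and silently average over the colonic
microbiome, even though fermentation of fiber and resistant starch into
short-chain fatty acids (SCFAs) is a genuine energy input to the host that
varies strongly between people and diets.

This package instead tracks food as **chemical oxygen demand** (COD): the
grams of O2 needed to fully oxidize a substrate. COD measures electron
equivalents, so host absorption and anaerobic microbial metabolism — which
does not use oxygen — can share a single conserved ledger. Every gram of
nutrient COD entering the mouth must leave as one of

* COD absorbed in the upper gastrointestinal tract (UGI),
* COD absorbed in the colon (SCFAs and residual fat),
* fecal COD (residual substrates, microbial biomass, unabsorbed SCFAs, fat),
* gaseous COD (methane, hydrogen).

Conservation of this ledger to numerical precision is the package's central
invariant and is enforced in the test suite on randomized inputs.

## Model structure

### Diet to gross COD

A food log (g wet weight per day) and a USDA-style composition table
(g nutrient per 100 g food) resolve the diet into individual nutrients:
amino acids, sugars, starch, resistant starch, fiber, saturated and
unsaturated lipids. Each nutrient's specific COD (gCOD/g) is its theoretical
oxygen demand, computed from the elemental formula `CcHhOoNn` by balancing
full oxidation with nitrogen terminating as ammonia:

    mol O2 = c + (h - 3n)/4 - o/2,   ThOD = 32 * mol O2 / molar mass.

Integer atomic masses (C = 12, H = 1, O = 16, N = 14) are used throughout so
that microbial biomass C5H7O2N has specific COD 160/113 = 1.42 gCOD/g, the
standard value in the anaerobic-treatment literature (exact masses would
print 1.41). Sulfur is not represented — no S-bearing species appears in the
reaction network — so cysteine and methionine are absent from the shipped
registry; their COD is in practice folded into the other amino acids by the
composition table. This is a documented limitation.

### Upper gastrointestinal tract

Direct enzymatic absorption is a per-nutrient fraction `alpha_N`:
absorbed `= alpha_N * gross`, to-colon `= (1 - alpha_N) * gross`, with zero
storage (orocecal transit of ~5 h is far below the one-day timescale of the
model). The shipped `alpha` defaults (`ugi_alpha_defaults_synthetic.yaml`)
are a literature-guided reconstruction: protein ~0.91, sugars 0.90–0.98,
digestible starch 0.90, fiber and resistant starch 0, fats 0.95. They are
plain YAML inputs meant to be overridden with study-specific digestibility
values; no result in this package depends on their exact magnitudes beyond
the qualitative ordering.

### The colon as a CSTR

The colon is one continuously stirred tank reactor whose solids retention
time equals the measured colonic transit time (CTT, days). All pools are
COD *amounts* (gCOD), effluent flux is `amount / CTT`, and microbial rates
are mixed second order, `k * S * X` with `k` in 1/(gCOD d) — matching the
units of the kinetic defaults:

| parameter | default | units | role |
|---|---|---|---|
| `k_p_hyd` | 5 | 1/(gCOD d) | protein (amino-acid) hydrolysis |
| `k_c_hyd` | 1 | 1/(gCOD d) | fiber / resistant-starch hydrolysis |
| `k_c_ferm` | 10 | 1/(gCOD d) | simple-sugar fermentation |
| `k_m` | 0.5 | 1/(gCOD d) | hydrogenotrophic methanogenesis |
| `k_f_abs` | 0.48 | 1/d | first-order colonic fat absorption |
| `K_scfa_abs` | 0.02 | d | CTT at which 50% of SCFAs are absorbed |

Hydrolysis is rate limiting and is fused with fermentation: hydrolyzed COD
converts directly to products through the stoichiometry row, with no free
monomer pool. Each substrate `N` then obeys

    dS/dt = Q_N - S/CTT - k S X,    dX/dt = Y k S X - X/CTT,

whose nontrivial steady state is `S* = 1/(Y k CTT)`,
`X* = Y CTT (Q_N - S*/CTT)`. When the influent falls below the washout
threshold `1/(Y k CTT^2)`, growth cannot match dilution and the closed form
switches to the washout branch `X* = 0`, `S* = Q_N CTT`. Because fermenter
inocula are not observable, the steady-state solution is the default; the
same balances are also exposed as an ODE system (`simulate_lgi_ode()`,
deSolve/lsoda, rtol 1e-10) which serves as an independent oracle — the test
suite checks closed form against long-horizon integration on 100 randomized
instances including forced washout cases.

### Fermentation stoichiometry

Fermentation conserves COD: with no external electron acceptor, 1 gCOD of
substrate becomes exactly 1 gCOD of products. A fraction `fs = 0.2` of donor
electrons goes to cell synthesis (biomass C5H7O2N); the remaining 0.8 splits
across acetate, propionate, butyrate and H2 in per-substrate catabolic
ratios. Carbohydrate fermentation is limited to the three SCFAs (no H2) by
default — a config flag reroutes part of the carbohydrate split to H2 for
sensitivity studies — while every amino acid contributes an H2 fraction.
The per-amino-acid ratios shipped in
`stoichiometry_defaults_synthetic.yaml` are a plausible reconstruction of
mixed-culture protein fermentation spectra and are deliberately plain
editable config: the package's conclusions are about the ledger mechanics,
not about any particular ratio set, and `validate_stoich_matrix()` checks
any replacement for row-wise COD conservation.

### Methanogenesis and the H2 chain

Hydrogenotrophic methanogens oxidize H2: per gCOD of H2 consumed,
`1 - fs_m` gCOD leaves as CH4 and `fs_m` becomes methanogen biomass. We set
`fs_m = 0.08`, a low anaerobic-autotroph yield; this is an open, configurable
choice. The acetate carbon methanogens assimilate is carbon bookkeeping
only; debiting biomass COD from donor electrons keeps the row
COD-conserving. The H2 pool satisfies
`H2* = R_prod / (k_m X_M + 1/CTT)`; unconsumed H2 leaves as gas, and all CH4
leaves as gas.

The methanogen pool `X_M` is **held fixed** at its seeded value during the
solve: methanogens grow far too slowly to reach a within-run steady state,
and only an initial estimate is observable. Their growth COD
(`fs_m * R_meth`) is routed to fecal biomass. Seeding converts fecal mcrA
qPCR copies to COD via cell geometry (cylinder 1.5 µm × 1 µm at 1 g/cm³ →
1.2e-12 g wet per cell, 20% dry, 90% organic, 1.42 gCOD/g), times a
retention factor (`X_M Factor`, colonic cells per fecal cell) that accounts
for methanogens held in epithelial biofilms. `fit_xm_factor()` calibrates
that factor by grid search (default grid 0.5–10, step 0.01 — fine enough to
resolve values near 2.5), minimizing the standard error of the estimate of
predicted vs measured daily methane COD, ties broken toward the smaller
factor. Observations below a configurable methane floor (default
0.01 gCOD/d) are excluded as methane-negative before fitting.

### SCFA and fat absorption

The absorbed share of microbially produced SCFAs follows a saturation
relationship in transit time, `e = CTT / (CTT + K_scfa_abs)`: longer contact
with the epithelium absorbs more, and at `CTT = K_scfa_abs` exactly half is
absorbed. Fecal SCFA is `(1 - e)` times production rather than a separate
CSTR balance — `e` is defined as absorbed mass normalized to produced mass,
so splitting production is the faithful reading and keeps the ledger exact.
Residual fat entering the colon is absorbed first order (`k_f_abs`)
in competition with washout; absorbed plus fecal fat equals influent fat
exactly.

## Baseline and agreement statistics

The Atwater baseline converts macronutrient grams to kcal (4/4/9; fiber
counted as carbohydrate, the classic convention) and then to gCOD with a
single configurable factor, default 3.2 kcal/gCOD — an approximation of
published energy↔COD regressions, exposed as configuration because no
per-macronutrient regression is hard-coded here.

Agreement of predictions with measurements is judged **against the identity
line**, not a fitted regression: `R2 = 1 - SS_err/SS_tot` (unbounded below),
`sigma_est = sqrt(mean((pred - meas)^2))` with denominator `n` because the
identity line estimates no parameters (a `df_correction` switch restores the
regression convention). Bland–Altman limits use the sample sd and a fixed
1.96 multiplier. Systematic bias is a one-sample t test of the differences
against zero; proportional bias is Kendall's tau (tie-corrected tau-b, since
the variant is otherwise unspecified) between per-pair means and
differences.

"Measured" metabolizable COD must be derived from measurable streams. The
default definition here is intake − fecal − CH4 − H2 (`"fecal_and_gas"`),
i.e. the same ledger definition the model uses for its prediction, so that
evaluating the model against its own noiseless synthetic measurements is
exactly R² = 1. The intake − fecal variant (`"fecal_only"`), which treats
gas losses as if they were metabolizable, is available behind
`cod_m_definition = "fecal_only"`; with real data the two differ by the
(small) gaseous COD. To support the gas-corrected definition the synthetic
measurement channels include breath/flatus H2 COD alongside CH4 — both are
measurable in practice (whole-room calorimetry, breath testing).

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` builds a fully self-contained randomized crossover
cohort: 17 participants × 2 diets, per-participant daily gross intake drawn
from N(630, 105²) gCOD/d, lognormal CTT with median 1.5 d (sdlog 0.4,
spanning the typical 1–2 day range), ~30% methanogen-positive participants
with lognormal fecal mcrA counts (median 5e11 copies), and a generating
retention factor of 2.58. The two menu templates are built from a dozen
synthetic composite foods and are energy-matched within participant; the
fiber + resistant-starch COD share is strictly higher on the MBD-like
(microbiome-enhancer) template than the WD-like (western) template for
every participant by construction. The template weights were chosen once so
that, at the default kinetics, the cohort reproduces realistic scales: mean
absorbed-SCFA COD ≈ 50 gCOD/d (MBD) vs ≈ 33 gCOD/d (WD), colon influent
10–15% of intake, fecal + gas losses 4–6% of intake.

Pseudo-measurements are the model's own outputs perturbed by multiplicative
Gaussian noise (5% fecal COD, 10% SCFA, 10% CH4, 10% H2 — biological
measurements scale with magnitude), truncated to stay positive. Because the
measurements are generated by the model itself, passing cohort-level tests
demonstrates *internal* consistency — ledger closure, calibration
recoverability, directional diet contrasts — and says nothing about
predictive accuracy on real people: real diets are not two fixed menus, real
fermentation spectra differ from the shipped ratios, and real measurement
error is not clean multiplicative Gaussian noise.

## Numerical choices and problem sizes

* Steady states are closed-form; no iteration, so the only tolerances are
  validation ones: stoichiometry rows conserve COD to 1e-9, ledgers are
  asserted to close within 1e-6 relative (they close to ~1e-15 in practice).
* The ODE oracle integrates to a 3000 d horizon with lsoda at rtol 1e-10 /
  atol 1e-12; randomized test instances keep influents well away from the
  washout threshold (below half or above double) so convergence is
  exponential and the 1e-6 comparison is meaningful.
* The grid search evaluates ~950 candidate factors against a closed-form
  methane chain, so calibration on a 34-row cohort takes well under a
  second.
* Test problem sizes: 100 randomized reactor instances for conservation and
  another 100 for oracle equivalence; calibration recovery at factors 1.0
  and 2.58, noiseless and at 10% noise; cohort-level checks on the default
  17 × 2 cohort. The full suite runs in well under a minute.

## Known limitations

* No sulfur chemistry, no pH/thermodynamic feedback on product spectra, no
  free-energy computation of half reactions.
* Single lumped fiber class; no spatial colon segmentation (a plug-flow
  variant is intentionally out of scope).
* No endogenous biomass decay; fermenter inocula assumed at steady state.
* Methanogen pool fixed within a run; dynamic methanogen growth is only
  reflected in the fecal-biomass ledger entry.
* The kcal↔COD factor is a single global configurable constant, not a
  per-macronutrient regression.
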