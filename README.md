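# damm

Mass-balance modelling of host energy absorption with an explicit colonic
microbiome.

## The problem

Standard metabolizable-energy accounting (the Atwater factors: 4, 4 and
9 kcal per gram of protein, carbohydrate and fat) treats the digestive tract
as a black box. It cannot represent the part of host energy that arrives via
microbial fermentation in the colon — short-chain fatty acids (SCFAs)
produced from fiber and resistant starch and absorbed by the colonic
epithelium — and therefore cannot respond to differences in diet, transit
time, or microbial community between people.

`damm` is for researchers in microbiome energy balance and nutrition
modelling who want a mechanistic alternative: it tracks dietary
macronutrients as **chemical oxygen demand** (COD, grams of O2 to fully
oxidize a substrate — a currency for electron equivalents that host
absorption and anaerobic microbial metabolism can share), and closes a
conserved ledger

```
COD_g(intake) = COD_m(UGI) + COD_m(LGI) + COD_f(feces) + COD_CH4 + COD_H2
```

for every person-diet.

## The model

1. **Diet → gross COD.** A food log plus a USDA-style composition table
   resolve the diet into individual nutrients (amino acids, sugars, starch,
   resistant starch, fiber, lipids). Each nutrient's specific COD is its
   theoretical oxygen demand from the elemental formula:
   `ThOD = 32 (c + (h - 3n)/4 - o/2) / MW` for `CcHhOoNn` (nitrogen leaves
   as NH3). Microbial biomass C5H7O2N has ThOD 1.42 gCOD/g.
2. **Upper GI.** Per-nutrient absorption fractions `alpha_N`; the remainder
   `(1 - alpha_N)` flows into the colon. Zero storage, exact balance.
3. **Colon = CSTR with SRT = CTT.** Per-substrate chemostat balances with
   mixed second-order kinetics `k S X`; closed-form steady states
   `S* = 1/(Y k CTT)`, `X* = Y CTT (Q - S*/CTT)` with an explicit washout
   branch, verified against a stiff ODE integration of the same balances.
4. **Fermentation stoichiometry.** COD-conserving rows: fraction
   `fs = 0.2` of donor electrons to biomass, the rest split across acetate,
   propionate, butyrate and (for amino acids) H2.
5. **Methanogenesis.** Hydrogenotrophs consume the H2 pool
   (`H2* = R_prod/(k_m X_M + 1/CTT)`) and release CH4 as gas. The
   methanogen pool is seeded from fecal mcrA qPCR counts times a biofilm
   retention factor (`X_M Factor`) that `fit_xm_factor()` calibrates by
   grid search against measured methane.
6. **Colonic absorption.** SCFA absorption is a transit-time saturation,
   `e = CTT/(CTT + K_scfa_abs)` (half absorbed at `CTT = 0.02 d`); residual
   fat is absorbed first order.

An Atwater baseline, identity-line agreement statistics (R², sigma_est,
Bland–Altman, one-sample t, Kendall tau) and a fully synthetic randomized
crossover cohort (two diet templates, lognormal transit times, mixed
methanogen carriage, noisy pseudo-measurements) make the whole pipeline
runnable and testable without any external data. See the methods vignette
(`vignettes/damm-model.Rmd`) for assumptions, parameter defaults and
limitations.

## Worked example

```r
library(damm)

co   <- generate_cohort(cohort_spec(seed = 1))   # 17 x 2 crossover cohort
diet <- cohort_diet_intake(co, "P01", "MBD")
row  <- subset(co$participants, participant_id == "P01" & diet_label == "MBD")

res <- run_damm(diet, ctt = row$ctt_days,
                x_m = xm0_from_mcra(row$mcra_copies,
                                    methanogen_params(xm_factor = 2.58)))
summary(res)
#> Digestion-absorption-microbial-metabolism run
#>   intake            564.22 gCOD/d
#>   UGI absorbed      479.94 gCOD/d (85.1%)
#>   into colon         84.29 gCOD/d
#>   LGI absorbed       57.20 gCOD/d (SCFA 49.97, fat 7.23)
#>   metabolizable     537.14 gCOD/d (95.2%)
#>   fecal              26.07 gCOD/d
#>   CH4 gas           0.0000 gCOD/d | H2 gas   1.0105 gCOD/d
#>   ledger rel err   0.0e+00
#>
#> SCFA ledger (gCOD/d):
#>          acetate propionate butyrate
#> produced 30.0121    12.4610   7.9284
#> absorbed 29.7551    12.3543   7.8605
#> fecal     0.2570     0.1067   0.0679
#>
#> SCFA absorbed fraction e = 0.991 at CTT = 2.32 d
```

For this fiber-rich menu, 85% of intake is absorbed directly in the small
intestine, 84 gCOD/d reaches the colon, and fermentation returns ~50 gCOD/d
of SCFA COD to the host (participant P01 carries no methanogens, so all
unconsumed H2 leaves as gas). The ledger closes exactly.

Cohort-level evaluation against noisy synthetic measurements shows the
structural result the model exists for — the Atwater baseline carries a
systematic bias that the mechanistic ledger does not:

```r
results <- run_damm_cohort(co, xm_factor = 2.58)
meas    <- simulate_measurements(co)
evaluate_predictions(results, meas, "atwater")
#> Metabolizable-COD agreement, method = atwater (measured as fecal_and_gas)
#>  treatment  n     r2 sigma_est mean_diff    t      t_p   tau    tau_p
#>        MBD 17 68.49%      50.0      47.7 12.9 7.02e-10 0.456 1.03e-02
#>         WD 17 74.75%      47.2      46.7 26.2 1.41e-14 0.647 1.28e-04
#>   combined 34 71.91%      48.6      47.2 23.4 4.25e-22 0.512 9.06e-06
```

and the methanogen retention factor is recoverable from measured methane:

```r
cal <- data.frame(mcra_copies = results$mcra_copies,
                  ctt_days = results$ctt_days,
                  h2_prod_gcod_per_day = results$h2_prod,
                  ch4_gcod_per_day = meas$ch4_gcod_per_day)
fit_xm_factor(cal)
#> Methanogen retention factor fit (grid search)
#>   X_M Factor: 2.44 (sigma_est 0.004596 gCOD/d, n = 4, 30 excluded)
```

(the cohort was generated with factor 2.58; 10% measurement noise on four
methane-positive observations lands the estimate at 2.44).

A thin shell entry point wraps the same functions:

```sh
Rscript inst/scripts/damm.R synth   --out runs/demo --seed 1
Rscript inst/scripts/damm.R run     --dir runs/demo --out runs/demo/results.csv --xm-factor 2.58
Rscript inst/scripts/damm.R compare --results runs/demo/results.csv \
    --measurements runs/demo/measurements.csv --out runs/demo/report.csv
Rscript inst/scripts/damm.R fit-xm  --results runs/demo/results.csv \
    --measurements runs/demo/measurements.csv --out runs/demo/fit
```

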