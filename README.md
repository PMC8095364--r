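# pm25emu

Gaussian-process emulation of a chemical-transport simulator's PM2.5
response to sectoral emission changes, with variance-based sensitivity
analysis and population-weighted exposure scenarios.

## The problem

Chemical-transport models (CTMs) such as WRF-Chem can predict how ambient
fine particulate matter (PM2.5) responds to emission changes, but a single
run is so expensive that only a handful of emission scenarios can ever be
explored directly. `pm25emu` implements the statistical-emulation
alternative for five anthropogenic emission sectors — residential (RES),
industry (IND), land transport (TRA), agriculture (AGR), and power
generation (ENE) — whose emission-scaling factors x ∈ [0, 1.5]⁵
(1.0 = baseline) form the input space:

1. **Experiment design** — maximin Latin hypercube designs over [0, 1.5]⁵;
   training size follows the 10-runs-per-input rule (50 runs for 5
   sectors), plus an independent held-out test design.
2. **Per-cell emulation** — for each grid cell, a Gaussian-process
   regression of the simulator's monthly-mean PM2.5 concentration on the
   five scaling factors, with Yeo–Johnson-transformed inputs, standardized
   outputs, and the Matérn 5/2 kernel
   k(r) = σ²(1 + √5 r/ℓ + 5r²/3ℓ²)·exp(−√5 r/ℓ),
   ARD lengthscales fitted by maximizing the log marginal likelihood.
3. **Evaluation** — k-fold cross-validation and held-out testing with R²,
   RMSE, and the factor metrics NMBF/NMAEF.
4. **Sensitivity analysis** — Saltelli sampling (run budget N(2D+2);
   12,000 emulator runs per cell at N = 1000, D = 5) and Sobol
   first-order (S1), second-order (S2), and total (ST) indices per cell
   and sector, presented as percentages and as absolute indices
   (S1 × baseline concentration).
5. **Exposure scenarios** — population-weighted exposure
   Σ popᵢCᵢ / Σ popᵢ for single- and two-sector emission sweeps
   (0–150% in 10% steps), flagged against the WHO Air Quality Guideline
   (10 µg m⁻³), WHO Interim Targets 1–3 (35/25/15), and China's National
   Air Quality Target (35 µg m⁻³).

Because CTM output is not redistributable, the package ships a
**synthetic simulator**: a deterministic per-cell polynomial response
surface with a positive non-anthropogenic background, near-linear sector
responses, interaction variance below 1% of the total, and *closed-form*
Sobol indices, so the entire pipeline can be validated against a
recoverable truth.

## Worked example

```r
library(pm25emu)

grid  <- grid_spec(4, 6, region_names = c("North China", "GBA", "South West China"))
truth <- build_truth(grid, region_profiles(), seed = 42)
pop   <- make_population(grid, seed = 43)

d_train <- lhs_maximin(training_size(5), 5, n_iter = 100, seed = 1)
d_test  <- lhs_maximin(5, 5, n_iter = 100, seed = 2, role = "test")
ems <- fit_grid(d_train, simulate_runs(truth, d_train), restarts = 5, seed = 3)

evaluate_emulators(ems, d_test, simulate_runs(truth, d_test))
#> eval_report (test)
#>   r2   rmse   nmbf nmaef
#> 1  1 0.0594 -3e-04 5e-04

sens <- sobol_grid(ems, N = 1024, seed = 4)
regional_summary(sens, grid, pop)
#>             region RES IND TRA AGR ENE n_cells
#> 1            China  56  22   6  16   0      24
#> 2              GBA  56  31   2  10   0       8
#> 3      North China  72  20   0   5   3       8
#> 4 South West China  53   8  13  25   1       8

round(baseline_exposure(ems, grid, pop), 1)
#>            China              GBA      North China South West China
#>             82.8             64.2            140.9            105.0

sw <- sweep_single(ems, "RES", grid, pop)
subset(sw, region == "China" & round(level, 1) %in% c(0, 0.7, 1),
       select = c(region, sector, level, exposure, AQG, NAQT))
#>    region sector level exposure   AQG  NAQT
#> 1   China    RES   0.0    51.79 FALSE FALSE
#> 29  China    RES   0.7    73.16 FALSE FALSE
#> 41  China    RES   1.0    82.84 FALSE FALSE
```

Reading the output: the 50-run emulators reproduce held-out simulator runs
almost exactly (pooled R² ≈ 1, RMSE ≈ 0.06 µg m⁻³ against baselines near
100 µg m⁻³). The recovered regional first-order percentages match the
profiles the synthetic grid was generated from (residential emissions
dominate; agriculture and land transport matter most in the South West).
The RES sweep shows exposure falling from 82.8 µg m⁻³ at baseline to
73.2 at a 30% residential reduction and 51.8 with the sector removed —
still far above both the 35 µg m⁻³ national target and the 10 µg m⁻³ WHO
guideline, because the other sectors and the non-anthropogenic background
remain.

`run_pipeline(default_config(...))` chains all stages and writes designs,
run sets, emulator tables, evaluation reports, sensitivity summaries,
sweep tables, and a JSON manifest of seeds and checksums to an output
directory.

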