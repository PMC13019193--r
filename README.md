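# sepsim

Simulation and feedback control of innate immune dynamics in sepsis.

`sepsim` is for computational systems biologists who want to study how
IL-6-responsive feedback interventions can steer a dysregulated innate
immune response back to resolution. It implements:

* a seven-species mass-action ODE model of pathogen invasion — pathogen,
  neutrophils, monocytes, M1/M2 macrophages, IL-6 and TGF-β — with a
  myeloid carrying-capacity factor and a switch-like effector gating the
  M1–pathogen interaction;
* eight IL-6-sensing Hill-type feedback controllers that multiply selected
  kinetic rates by `1 + α·IL6ⁿ/(Kdⁿ + IL6ⁿ)` (single-, dual- and
  triple-target laws);
* the full in-silico campaign toolkit: virtual-cohort global sensitivity
  scans with acute/septic day-8 classification, controller hyperparameter
  grid optimization (168 cells), Latin-hypercube ±50% robustness analysis,
  and secondary-infection stress tests;
* least-squares calibration of the kinetics to neutrophil/M1/M2 time
  courses, one-at-a-time local sensitivity ranking, and a seeded synthetic
  time-course generator.

The model, in the field's standard notation (all rates per day, species in
arbitrary units):

```
dP/dt   = α₂·M1·P·eff(M1) − γ₄·N·P − δ₃·P
dN/dt   = α₁·Pⁿ/(Pⁿ+Knⁿ)·cap − γ₅·N·IL6 − μ₁·N
dMo/dt  = γ₅·N·IL6 − γ₂·Mo − μ₂·Mo
dM1/dt  = γ₂·Mo − γ₃·M1·TGFβ − μ₃·M1
dM2/dt  = γ₃·M1·TGFβ − μ₄·M2
dIL6/dt = β·N − δ₁·IL6
dTGFβ/dt= γ₁·M1·N − δ₂·TGFβ

cap     = max(0, 1 − (N+Mo+M1+M2)/Cmax)
eff(M1) = tanh(κ·(M1 − θ_eff)/2)
```

A run is classified **acute** when at least 90% of the initial pathogen
load is cleared by day 8 (a 20 a.u. load down to ≤ 2 a.u., boundary
inclusive), **septic** otherwise. A controller's success rate is the
fraction of originally septic scenarios it reverts to acute.

The bundled nominal parameter set
(`inst/extdata/synthetic_nominal.json`) is **synthetic** — a stand-in
chosen for qualitative realism, since the original fitted calibration
table is not redistributable. See the methods vignette
(`vignettes/sepsis-feedback-control.Rmd`) for every magnitude's rationale
and for what the tests do and do not establish.

## Worked example

```r
library(sepsim)

params <- nominal_parameters()
traj <- integrate_model(params, immune_state(pathogen = 20), horizon = 8)
traj
#> <sepsim_trajectory> 801 samples over [0, 8] days (802 steps)
#>   controller: none
#>   final state: pathogen=1.42, neutrophil=0.77, monocyte=0.0702, M1=0.527,
#>                M2=0.0752, IL6=0.226, TGFb=0.178
classify(traj)
#> <simulation_outcome> acute: pathogen(day 8) = 1.418, clearance = 92.9%
```

The nominal invasion resolves acutely: 92.9% of the 20 a.u. load is
cleared by day 8. A virtual cohort scales all 19 varied parameters by
uniform factors in [0.1, 10]:

```r
scen <- sample_cohort(params, n_samples = 200, seed = 7)
res  <- run_cohort(scen, dt = 0.02)
res
#> <campaign_result> 200 scenario(s), 0 failed
#>   acute (success) fraction: 84.5%
```

Most virtual patients clear the infection; 31 of these 200 are septic.
Applying the M1-clearance controller (`ck1`, gain α = 10, cooperativity
n = 1, threshold Kd = 0.2 a.u. IL-6) to the septic subset:

```r
septic  <- scenario_subset(res, "septic")
rescued <- run_cohort(septic, controller = named_controller("ck1"), dt = 0.02)
rescued
#> <campaign_result> 31 scenario(s), 0 failed
#>   acute (success) fraction: 58.1%
```

i.e. the controller reverts 58% of this cohort's septic runs to acute
healing. The actuation itself is a shared Hill multiplier — at IL-6 equal
to the threshold, each target rate of the triple-target law runs at
1 + α/2 = 6× its uncontrolled value:

```r
multipliers_for_state(immune_state(IL6 = 0.2), named_controller("triple"))
#>    mu3 delta3    mu2 gamma3
#>      6      6      1      6
```

Grid optimization, robustness and secondary-infection campaigns follow the
same pattern (`optimize_grid()`, `robustness_lhs()`,
`secondary_infection_campaign()`); calibration uses
`generate_synthetic_timecourse()` / `fit_parameters()` /
`local_sensitivity_ranking()`.

## Command line

Each campaign is scriptable via `exec/sepsim`:

```sh
Rscript exec/sepsim scan      --seed 1 --out results/scan
Rscript exec/sepsim optimize  --config my_config.yaml --out results/opt
Rscript exec/sepsim fit       --params my_params.json --out results/fit
```

Commands: `simulate`, `scan`, `optimize`, `robustness`, `secondary`,
`fit`. Configuration files (JSON or YAML) overlay `default_config()`,
whose defaults reproduce the reference campaign settings (pathogen load
20 a.u., 8-day horizon, 1000-scenario cohort over [0.1, 10]×, 168-cell
grid, 100-set ±50% LHS, controller at α = 10 / n = 1 / Kd = 0.2). Every
run writes full-precision CSV tables, a JSON summary and a manifest with
the derived child seeds; artifacts are byte-identical under a fixed
(config, seed).

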