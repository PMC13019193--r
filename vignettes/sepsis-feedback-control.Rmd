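---
title: "Modeling sepsis dynamics and IL-6 feedback control with sepsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sepsis dynamics and IL-6 feedback control with sepsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsim)
```

## The model

`sepsim` implements a deterministic, well-mixed ODE model of the innate
immune response to a pathogen load, built from mass-action kinetics over
seven species: pathogen $P$, neutrophils $N$, monocytes $M_o$,
pro-inflammatory macrophages $M_1$, anti-inflammatory macrophages $M_2$,
IL-6, and TGF-$\beta$. Time is measured in days, concentrations and cell
counts in arbitrary units (a.u.):

$$
\begin{aligned}
\dot P   &= \alpha_2 M_1 P\,\mathrm{eff}(M_1) - \gamma_4 N P - \delta_3 P\\
\dot N   &= \alpha_1 \frac{P^{n}}{P^{n}+K_n^{n}}\,\mathrm{cap}
            - \gamma_5 N\,\mathrm{IL6} - \mu_1 N\\
\dot M_o &= \gamma_5 N\,\mathrm{IL6} - \gamma_2 M_o - \mu_2 M_o\\
\dot M_1 &= \gamma_2 M_o - \gamma_3 M_1\,\mathrm{TGF} - \mu_3 M_1\\
\dot M_2 &= \gamma_3 M_1\,\mathrm{TGF} - \mu_4 M_2\\
\dot{\mathrm{IL6}} &= \beta N - \delta_1\,\mathrm{IL6}\\
\dot{\mathrm{TGF}} &= \gamma_1 M_1 N - \delta_2\,\mathrm{TGF}
\end{aligned}
$$

with two auxiliary nonlinearities:

* **capacity**, $\mathrm{cap} = \max\{0,\, 1 - (N+M_o+M_1+M_2)/C_{\max}\}$,
  a shared myeloid carrying-capacity factor limiting neutrophil recruitment.
  The clamp at 0 is a deliberate choice: past capacity the recruitment flux
  stops rather than becoming a biologically meaningless sink
  (`capacity()`).
* **effector**, $\mathrm{eff}(M_1) = \tanh\!\big(\kappa (M_1 -
  \theta_{\mathrm{eff}})/2\big)$, a switch in $(-1,1)$ crossing zero at the
  activation threshold $\theta_{\mathrm{eff}}$. The `tanh` form is
  algebraically identical to the shifted logistic
  $2/(1+e^{-\kappa(M_1-\theta_{\mathrm{eff}})})-1$ and cannot overflow
  (`effector()`).

Two structural readings deserve a note, because the model's prose
description and its printed equations can be reconciled in more than one
way:

* **The sign of $\alpha_2$.** The $\alpha_2 M_1 P\,\mathrm{eff}(M_1)$ term
  is implemented exactly as written, and $\alpha_2$ is the one parameter
  allowed to carry either sign. The bundled nominal set uses
  $\alpha_2 < 0$: below the activation threshold the effector is negative,
  so the term is a *growth* term — abundant but ineffective $M_1$
  (immune paralysis) lets the pathogen expand — while above threshold it
  turns into clearance. This is the only reading under which the system has
  an exponential septic growth phase at all (there is no other pathogen
  gain term), and it is what makes removing $M_1$ a sensible intervention.
* **The Hill denominator.** Neutrophil recruitment uses
  $P^{n}/(P^{n}+K_n^{n})$, so $K_n$ is a half-saturation concentration for
  every Hill coefficient $n$ (recruitment is exactly $\alpha_1/2$ at
  $P = K_n$). The alternative reading $P^{n}+K_n$ would give $K_n$ units of
  a.u.$^n$ and break that anchor for $n \neq 1$.

### Parameters

All 20 constants live in a `model_parameters` vector; rates are per day.
The bundled `nominal_parameters()` set is **synthetic**: the original
calibration table of the murine peritonitis fit is not redistributable, so
the package ships a stand-in chosen once for qualitative realism and then
frozen. The choices, and why:

| parameter | value | rationale |
|---|---|---|
| $\alpha_1 = 30$, $K_n = 10$, $n = 2$ | neutrophil recruitment | a 20 a.u. invasion recruits an $\mathcal{O}(10)$ neutrophil burst within a day, saturating at high load |
| $\gamma_5 = 0.3$, $\beta = 0.5$, $\delta_1 = 2$ | IL-6 axis | IL-6 tracks the neutrophil burst with a short half-life; nominal excursions of 0.2–2 a.u. put the controller threshold grid $K_d \in [0.2, 1.5]$ on the raw IL-6 scale |
| $\gamma_2 = 1$, $\mu_2 = 0.3$, $\mu_3 = 0.5$, $\mu_4 = 0.5$ | myeloid turnover | a delayed monocyte $\to M_1 \to M_2$ wave peaking around day 3 |
| $\gamma_1 = 0.05$, $\delta_2 = 0.5$, $\gamma_3 = 0.1$ | TGF-$\beta$ axis | slow accumulation, acting as the delayed brake that drives $M_1 \to M_2$ resolution |
| $\alpha_2 = -0.15$, $\theta_{\mathrm{eff}} = 5$, $\kappa = 1$ | effector-gated interaction | nominal $M_1$ stays below threshold, so the septic growth route exists but is dominated by clearance at nominal rates |
| $\gamma_4 = 0.1$, $\delta_3 = 0.2$, $\mu_1 = 1$, $C_{\max} = 60$ | clearance & limits | the nominal invasion resolves with ~93% clearance by day 8 — acute, with margin from the 90% boundary |

With these values a 1000-scenario global scan (every parameter except $n$
scaled by independent uniform factors in $[0.1, 10]$) produces a
majority-acute, minority-septic cohort, reproducing the qualitative
clinical picture the model is meant to emulate. The split and the
controller success rates are properties of this synthetic world and are
**not** the published numbers from the original fitted world; the test
suite therefore asserts structure (counts, determinism, monotonicities,
classification rule) rather than those headline percentages. Notably, in
this world boosting intrinsic pathogen removal (`ck2`) outperforms $M_1$
clearance (`ck1`) among single-target laws, whereas the original fitted
world reports the reverse; multi-target laws dominate and the
$M_2$-promoting law is weakest in both.

## Simulation and classification

`integrate_model()` advances the system with an adaptive embedded
Dormand–Prince 5(4) pair (compiled; error per step controlled by
`rtol = 1e-6`, `atol = 1e-9` by default) and samples the solution on a
uniform grid of 0.01-day resolution. Numerical choices:

* tiny negative excursions are projected to 0 both inside the right-hand
  side and before storage, keeping the nonnegative orthant invariant;
* pulse perturbations (`pulse_event()`) split the integration exactly at
  the event time and add their amount to one species, so additivity is
  exact to the bit; when an event coincides with a grid time, the stored
  state is post-pulse;
* a step-budget or step-underflow failure raises a diagnostic error rather
  than returning a silently truncated trajectory; campaign drivers record
  such scenarios and exclude them from success-rate denominators with a
  warning (a solver failure is not biology — counting it either way would
  bias rates).

`classify()` reads the pathogen level at $t = 8$ days exactly (not the
running minimum — trajectories may dip and rebound) and labels a run
*acute* when at least 90% of the initial load has been cleared, boundary
inclusive: from a 20 a.u. load, a day-8 level of exactly 2 a.u. is acute.
Initial conditions other than the pathogen load default to a resting
system (all other species 0): the extinction equilibrium plus a 20 a.u.
pulse is the invasion scenario, and the resting state is configurable for
users who want pre-activated compartments.

## Feedback controllers

A controller senses the model's IL-6 level directly and instantaneously
(no sensor dynamics — the sensing circuit is conceptual) and multiplies
each rate in its target set by the shared Hill term

$$ u(\mathrm{IL6}) = 1 + \alpha\,
   \frac{\mathrm{IL6}^{\,n_c}}{K_d^{\,n_c} + \mathrm{IL6}^{\,n_c}}, $$

so every actuated rate is scaled between $1\times$ (no signal) and
$(1+\alpha)\times$ (saturating signal). The bracketed-list notation of the
multi-target laws is read as elementwise application of this single shared
multiplier — the dual and triple laws deliberately reuse one Hill term
rather than one per rate. The eight named laws and their actuation points:

| name | targets | mechanism |
|---|---|---|
| `ck1` | $\mu_3$ | accelerate $M_1$ clearance |
| `ck2` | $\delta_3$ | boost innate pathogen removal |
| `ck3` | $\mu_2$ | deplete the monocyte reservoir |
| `ck4` | $\gamma_3$ | promote $M_2$ polarization |
| `dual1` | $\mu_3,\delta_3$ | combine `ck1` + `ck2` |
| `dual2` | $\mu_3,\gamma_3$ | combine `ck1` + `ck4` |
| `dual3` | $\gamma_3,\delta_3$ | combine `ck4` + `ck2` |
| `triple` | $\mu_3,\delta_3,\gamma_3$ | all three |

Default hyperparameters are $\alpha = 10$, $n_c = 1$, $K_d = 0.2$, the
highest-gain, lowest-threshold corner of the standard optimization grid.
Integral or derivative action, actuation delays and multi-biomarker
sensing are out of scope by design.

## Campaigns

* **Global scan** (`sample_cohort()` + `run_cohort()`): independent
  uniform factors on $[0.1, 10]$ for the 19 varied parameters (the Hill
  coefficient is held fixed so the scan perturbs rates and thresholds on a
  common multiplicative scale), 1000 scenarios by default, each a 20 a.u.
  invasion classified at day 8.
* **Grid optimization** (`optimize_grid()`): success rate per cell of the
  $7 \times 4 \times 6 = 168$-cell $(\alpha, n_c, K_d)$ grid over a septic
  scenario set. Ties are broken deterministically toward the least
  aggressive controller: smaller $\alpha$, then smaller $K_d$, then
  smaller $n_c$.
* **Robustness** (`robustness_lhs()`): per septic scenario, a Latin
  hypercube (one draw per equal-probability stratum per dimension —
  hand-rolled, and tested combinatorially) of $\pm 50\%$ factors on the
  six most impactful rates $\{\mu_3, \mu_4, \delta_1, \gamma_3, \beta,
  \delta_3\}$, 100 sets each. Whether the perturbation is relative to each
  scenario's own values (default) or to a common nominal base is ambiguous
  in the source description; both are supported via `relative_to`.
  Stratified summaries bin each factor into low (0.5–0.8×), nominal
  (0.8–1.2×) and high (1.2–2.0×); a factor outside $[0.5, 2]$ —
  impossible under $\pm 50\%$ — is an error, not a silent drop.
* **Secondary infection** (`secondary_infection_campaign()`): a seeded
  uniform sample of controller-rescued runs (the selection rule is
  otherwise unspecified) is re-simulated under each of the
  $5 \times 6 = 30$ (load %, injection day) pulse combinations. The
  clearance clock starts at the pulse, resolved on the trajectory grid,
  since the origin of that clock is not pinned down by the source
  description.

One master seed expands into per-campaign child seeds through a documented
affine map (`child_seed()`), so each campaign is independently
reproducible and all artifacts are byte-stable under a fixed
(config, seed) pair.

## Calibration

`fit_parameters()` minimizes the joint squared residual of the neutrophil,
$M_1$ and $M_2$ time courses. Each species' residuals are normalized by
that species' maximum observed value before summing — the observed
magnitudes can differ by orders of magnitude and no weighting scheme is
prescribed, so equal *relative* weight per species is the neutral choice
(per-point weights can override it). The optimizer is L-BFGS-B on the log
of each free parameter's magnitude (signs fixed by the initial guess),
with optional seeded multistarts drawn log-uniformly within bounds; the
best-so-far residual trace is recorded and is non-increasing by
construction. This replaces the original interior-point solver, of which
only the name is known.

`local_sensitivity_ranking()` ranks parameters by the normalized central
difference $(\Delta M / M)/(\Delta\theta/\theta)$ at $\pm 10\%$, with the
day-8 pathogen level as the default metric — the exact metric and step of
the original supplementary analysis are not published, so both are
configurable. A zero baseline metric switches to absolute sensitivities
with a warning.

`generate_synthetic_timecourse()` is the fixture generator standing in for
the unavailable murine dataset: exact model output times a log-normal
multiplier whose coefficient of variation equals `noise_level`
($\sigma_{\log} = \sqrt{\log(1+\mathrm{CV}^2)}$), seeded. Real cell-count
data additionally carry sampling-time jitter, animal-to-animal parameter
variation and non-multiplicative counting error; none of these are
emulated, so a green parameter-recovery test establishes that the fitting
machinery works on well-specified data, not that the original experimental
calibration is reproduced.

## What the tests do and do not establish

The suite proves: the kinetics match their stated algebra (including a
hand-expanded oracle and a compiled-vs-interpreted equivalence check); the
integrator agrees with an independent fixed-step RK4 oracle to $10^{-4}$;
events are exactly additive; controllers are exact Hill laws with the
stated anchors, bounds and target maps; campaign counts, seeds, artifacts
and tie-breaks are exactly as specified; and noiseless synthetic fits
recover generating parameters to 1%.

It does not prove the published cohort percentages (90.6% acute, the
85/70/17/2% single-controller and 89/91/95/72% multi-controller success
rates, the 82.2% pooled robustness rate, or the 20% secondary-infection
rate): those are facts about the original fitted parameter table, which is
not available to this package. With the synthetic nominal world the same
machinery yields a different (but qualitatively similar) set of numbers,
recorded by the scaled campaign runs in the acceptance tests.

## Known limitations

* No spatial structure, stochastic kinetics, delay terms or additional
  cytokines; pulses only (no infusions).
* The effector/capacity forms make the right-hand side non-smooth at the
  capacity boundary; the adaptive integrator handles this by error
  control, not by event location.
* Identifiability is not analyzed; fits with more than ~6 free parameters
  on three observables can be degenerate, which is why the calibration
  examples restrict the free set.
* The synthetic nominal world differs from the original fitted world in at
  least one ranked outcome (single-controller ordering); conclusions about
  *which* intervention is best do not transfer, only the methodology.
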