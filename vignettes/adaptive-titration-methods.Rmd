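---
title: "Myelosuppression PK-PD modelling and model-based dose titration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelosuppression PK-PD modelling and model-based dose titration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelotitr)
```

# The problem

Decitabine maintenance after allogeneic stem-cell transplantation walks a
narrow line: the dose should be as high as tolerable (hypomethylating
exposure), but grade-4 hematologic toxicity — an absolute neutrophil count
(ANC) below 500/mm³ or a platelet count (PC) below 25,000/mm³ — endangers
the graft. `myelotitr` implements the quantitative machinery of an
adaptive phase-I design built around this trade-off: a population PK-PD
model of drug-induced myelosuppression, empirical-Bayes individual
fitting, and a simulation-based dose-selection rule applied per patient
and per cohort, plus a virtual-trial engine to stress-test the whole
design.

# The model

## Disposition

Plasma decitabine follows linear two-compartment kinetics with zero-order
(infusion) input. Parameters are expressed per m² of body surface area
(BSA): a subject's absolute clearance and volumes are the per-m² values
times BSA, and doses are prescribed in mg/m². The ratio makes the
typical-subject concentration curve BSA-invariant, which the package
exploits throughout. Because the system is linear,
`predict_concentration()` uses the closed-form biexponential infusion
solution superposed over dose events; this analytic path is the reference
implementation and `auc_per_cycle()`'s dose/CL identity and an ODE
cross-check pin it down in the tests.

## Myelosuppression

Each toxicity marker (ANC, PC) follows a five-compartment transit chain: a
proliferating pool $A_1$, three transit compartments, and the observable
circulating pool $A_5$, all coupled by a common rate constant $k_{tr}$:

$$\frac{dA_1}{dt} = k_{tr} A_1 \left[(1 - \mathrm{SLOPE}\cdot C)\,
  (B(t)/A_5)^{\gamma} - 1\right], \qquad
  \frac{dA_k}{dt} = k_{tr}(A_{k-1} - A_k),\; k = 2\dots 5.$$

Drug effect is linear in concentration; $(1-\mathrm{SLOPE}\cdot C)$ is
deliberately allowed to go negative (net cell kill), which at the
estimated neutrophil slope and typical end-of-infusion concentrations
(about 51 ng/mL) is the operative regime. The feedback term
$(B/A_5)^\gamma$ accelerates production when circulating counts fall below
the baseline target $B(t)$, producing the characteristic rebound above
baseline after the nadir.

For neutrophils $B(t) = \mathrm{BASE}$. For platelets the baseline target
itself recovers over treatment,

$$B(t) = \mathrm{BASE} + \mathrm{IMP}\,(1 - e^{-\mathrm{IMK}\,t}),$$

with $t$ the time since the subject's first dose (not since cycle start).
$B(t)$ is substituted only inside the feedback ratio — the one place BASE
appears in the dynamics. All compartments are initialised at BASE for both
markers; for platelets the time-varying target makes the zero-dose system
non-stationary by construction, so the drug-free platelet trajectory
drifts monotonically towards BASE + IMP rather than staying flat. The
drug-free ANC trajectory is an exact fixed point.

## Random effects and residual error

Individual parameters are lognormal,
$P_{ij} = \mathrm{TVP}_j\,e^{\eta_i}$, $\eta_i \sim N(0, \omega_j^2)$,
independently per parameter; parameters whose variability was not
estimable stay at their typical values. Variability is configured as CV%;
the default convention is the pharmacometric shorthand
$\omega = \mathrm{CV}/100$, with the exact-lognormal alternative
($\omega^2 = \log(1+\mathrm{CV}^2)$) available by flag since the reporting
convention is not stated with the estimates.

Observations follow $DV = \mathrm{IPRED}(1+\varepsilon_{prop}) +
\varepsilon_{add}$, with only the proportional term used for
concentrations and only the additive term for counts, matching the final
reported error model. The additive count variances are used exactly as
printed even though they are strikingly small for the platelet/neutrophil
scales involved (SD ≈ 158/mm³ and ≈ 27/mm³); both are config-overridable.
Concentrations below the 0.5 ng/mL quantification limit are dropped by
default, with an M3-style censored-likelihood option.

# Numerical choices

The concentration enters the cell-count ODE analytically, so only the
five (or ten, when both markers are simulated jointly) cell compartments
are integrated. That system is not stiff — its rates are of order
$k_{tr} \sim 0.01\text{--}0.02\,h^{-1}$, with brief excursions during the
1-h infusions — so the package integrates it with an adaptive
Dormand-Prince 4(5) pair implemented in compiled code, split piecewise at
infusion boundaries (where the right-hand side has corners) and with cubic
Hermite dense output at requested times. The default relative tolerance is
1e-8 for user-facing simulation; the titration simulations run at 1e-5,
which moves nadir values by well under 0.1% (the tolerance-refinement test
asserts this) while making 500-replicate-per-candidate-dose selection
cheap. An independent `deSolve::lsoda` integration of the same equations,
driven by the R implementation of the right-hand side, serves as the
oracle in the test suite; the two routes agree to ~1e-7 relative.

A replicate whose parameter draw drives the circulating pool into
numerical collapse (counts underflowing toward zero faster than the
integrator can follow) is recorded as a zero nadir — a
catastrophic-toxicity draw — rather than an error; this only occurs for
extreme draws from wide estimation-uncertainty covariances and makes the
percentile criterion conservative for them.

`find_nadir()` scans a 6-h grid and refines the minimum by a local
quadratic fit, breaking ties at the earliest time. The trajectory varies
on a multi-day scale, so the grid-plus-refinement error is negligible
relative to every threshold involved.

# Estimation

NONMEM's FOCE-I is not reimplemented. Individual fitting is MAP /
empirical-Bayes: minimise

$$-2\log L(\mathrm{data}\mid \eta) + \sum_j \eta_j^2/\omega_j^2$$

over the log-scale deviations $\eta$ of the parameters with estimated
variability (positivity is automatic). The likelihood uses variance
$\mathrm{IPRED}^2\sigma^2_{PK}$ for concentrations and the marker's
additive variance for counts.

Optimisation is Nelder-Mead on the unconstrained $\eta$ scale with up to
5 jittered multi-starts (tie-break: lowest objective, then
lexicographically smallest vector). One numerical point deserves emphasis:
the near-noiseless count data make the likelihood surface a narrow curved
ridge trading clearance against the drug-effect slopes (both enter the
cell-kill term essentially through SLOPE × AUC), and a single Nelder-Mead
run tends to collapse its simplex on that ridge far from the optimum. The
optimiser therefore restarts at its incumbent (re-expanding the simplex)
until the objective stops improving, up to 5 restarts of at most 1000
simplex iterations at relative tolerance 1e-8. With restarts, individual
clearance and neutrophil slope are recovered within 25% for essentially
every subject simulated under the study's sampling design; without them,
for only about half.

The curvature (numerical Hessian) of the objective at the optimum supplies
an approximate covariance of the estimates — the posterior approximation
from which the titration machinery draws.

Population re-estimation is a deliberately simple iterated two-stage
procedure: MAP-fit every subject against the current population values,
set each typical value to the geometric mean of the individual estimates,
each BSV variance to the sample variance of the log-estimates, re-estimate
residual variances from pooled residuals, and repeat to a fixed point
(default at most 4 iterations, 1% log-scale tolerance). MAP shrinkage
biases the BSV variances low — the standard caveat for two-stage methods —
which in cohort dose estimation makes the simulated population tighter and
the selected starting dose somewhat higher than a full mixed-effects fit
would give. This is a known, documented limitation, not a target of the
acceptance checks.

# Dose selection

`select_cycle_dose()` implements the trial's rule: among candidate doses
on a 0.5 mg/m²/day grid (0–15 by default, matching every dose actually
administered in the study), select the maximum dose whose lower 50%
prediction bound — the 25th percentile (type-7, linear interpolation, a
deliberate and documented estimator choice at n = 500) over 500 simulated
replicates of the upcoming cycle appended to the subject's realised dosing
history — keeps the ANC nadir ≥ 500/mm³ and the PC nadir ≥ 25,000/mm³ over
a six-week window; then clip to 150% of the previous dose. The six-week
window covers the model-predicted 3.5-week time-to-nadir with margin,
including carry-over from the previous cycle.

What varies across the 500 replicates is a design decision the protocol
text leaves open. The package draws parameter vectors from the
individual's estimation uncertainty (multivariate normal on log-parameter
deviations, using the fit covariance) for individual titration, and
fresh subjects with full between-subject variability for cohort dose
estimation; residual error is excluded because nadirs are model states,
not noisy observations. Both choices are config-selectable
(`uncertainty = "estimation" | "bsv" | "none"`). Replicate draws are made
once per decision and reused across candidate doses (common random
numbers), and because the percentile nadir is monotone non-increasing in
dose, a bisection search option locates the qualifying boundary in
O(log) probes — used inside virtual trials, where the full decision table
is not needed.

Fresh virtual subjects for cohort dose estimation are screened by the
study's enrolment criteria (baseline PC > 30,000/mm³, ANC > 1000/mm³).
This matters: with the estimated 105% CV on baseline platelets, roughly a
quarter of unscreened lognormal draws would start below the grade-4
platelet threshold, a state no dose rule can avoid and one the study
excluded by design.

# The virtual trial engine

`run_virtual_trial()` replays the design end-to-end: cohorts on a common
starting dose (5 mg/m²/day for cohort 1; model-estimated per cohort
thereafter, pooling all prior data for cohort 2 and Cycle-1 data only for
later cohorts), 1-h infusions on days 1–5 of 28-day cycles, seven PK
samples on Cycle-1 Day-1 (pre-dose and 20–180 min), weekly counts, MAP
refit and individual titration before each of Cycles 2–4, the Cycle-4
dose maintained thereafter, and a new cohort gated on the previous
cohort's Cycle-1 completion. Dosing is suspended in weekly steps while the
most recent observed counts sit below the recovery thresholds
(PC < 30,000/mm³ or ANC < 1000/mm³); a subject undosed for 12 weeks
discontinues. Within-trial refits warm-start at the previous cycle's
estimate with a single optimisation start — sequential refitting on
smoothly accruing data does not need the cold multi-start — and run the
integrator at the titration tolerance.

Noisy observed counts drive suspension and refitting; noise-free
trajectories define the dose-limiting-toxicity flags (a conservative
convention — the continuous trajectory catches nadirs weekly labs might
miss; a labs-only mode is available). The DLT window for a cycle runs from
its first dose to the next cycle's first dose (plus six weeks for the last
cycle); with 28-day spacing the 3.5-week nadir of a cycle's own dose falls
inside its own window. Percentages in `summarize_safety()` round half-up
to one decimal, matching the published accounting convention. Everything
is driven by deterministic child seeds: identical seed and configuration
give bit-identical records.

# The synthetic-data generator

`generate_synthetic_study()` emulates the study conditions: BSA drawn from
Normal(1.7, 0.2) m² (truncated positive), lognormal BSV at the published
CV%s, the published residual-error variances, seven PK samples at
0/20/40/60/90/120/180 min of Cycle-1 Day-1, weekly counts until Cycle 4
and biweekly thereafter, and BQL flagging at 0.5 ng/mL. What it does *not*
emulate: eligibility-driven enrolment flow, transfusions or growth
factors, concomitant-medication effects on counts, assay drift, missed
visits, or any efficacy endpoint. Passing tests on these data show that
the machinery is internally consistent under the model that generated
them — a necessary condition, not evidence about real patients.

# Problem sizes and frozen conditions

The packaged checks use, as the package's own choices: a 12-week, 6-h
grid for the typical-individual nadir; a 200-subject single-cohort
virtual trial (fixed 5 mg/m²/day start, Cycles 1–4) for the design's 25%
calibration guarantee; 20 seeds × 12 subjects with dense sampling
(12 PK samples to 6 h, counts every 3.5 days) for two-stage recovery of
typical clearance; and 50 single-cycle subjects under the study design
for individual MAP recovery. Simulation sizes in the titration rule
itself (500 replicates, 25th percentile, 0.5-step grid, 150% cap) are the
study's stated conditions and are never tuned.

# Known limitations

* Two-stage population refitting underestimates BSV (shrinkage); no full
  mixed-effects alternative is provided by design.
* The estimation-uncertainty covariance is a Laplace approximation; for
  subjects with a single cycle of data it can be wide enough that extreme
  replicate draws hit the zero-nadir guard, which is conservative.
* The interim one-compartment model configuration used early in the real
  study is supported structurally (`n_compartments = 1`) but has no
  numeric fixture, since its prior parameter values are not published.
* Drug effect is linear only; no alternative myelosuppression structures.
* Correlated BSV, covariate submodels, and inter-occasion variability are
  out of scope.
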