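---
title: "A hybrid multi-scale model of castration-resistant prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid multi-scale model of castration-resistant prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hmsm` simulates the progression of a prostate tumor through androgen
deprivation therapy (ADT, "castration") and the emergence of
castration-resistant prostate cancer (CRPC) inside an explicitly simulated
immune microenvironment. It couples three scales:

* **Intracellular** — a five-species ODE system describing how the
  extracellular ligands WNT5A and EGF drive androgen-receptor (AR)
  signaling through two branches (WNT5A→ERK→AR and EGF→Skp2→AKT→AR) and,
  downstream of AR, a proliferation readout. Each stage is a saturating
  Hill activation minus first-order decay:

  $$\frac{d[\mathrm{ERK}]}{dt} = k_1\frac{W}{H_1+W} - d_1[\mathrm{ERK}],
  \qquad
  \frac{d[\mathrm{AR}]}{dt} = (1-D_1)k_4\frac{[\mathrm{ERK}]}{H_4+[\mathrm{ERK}]}
  + (1-D_2)k_5\frac{[\mathrm{AKT}]}{H_5+[\mathrm{AKT}]} - d_4[\mathrm{AR}],$$

  and so on (see `signaling_rhs()`). $D_1$ and $D_2$ are pathway blockade
  fractions (an EGFR inhibitor sets $D_2$). Ligand doses are normalized to
  $[0,1]$, where 1 is the maximal experimental dose. The model's output is
  the *proliferation fold change* relative to no stimulation.

* **Intercellular** — lattice agents for tumor cells (PC), tumor-associated
  macrophages (TAM), cytotoxic CD8+ T cells (CTL), regulatory T cells
  (Treg) and endothelial sprout tips (EC), with probability-threshold
  ("dice") decisions every 2 hours, at most one cell per site.

* **Tissue** — reaction–diffusion fields for WNT5A, EGF, CSF1, VEGF, IL10,
  IL-2 and TRAIL (explicit 7-point stencil, zero-flux boundaries,
  first-order decay), a two-compartment androgen level, a lymph-node
  compartment with a programmed dendritic-cell/T-cell activation cycle, and
  tumor-induced angiogenesis from a parent vessel.

The cell–cell interaction circuitry follows the CRPC hypothesis the model
encodes: castration lowers androgen, androgen-dependent tumor cells die and
release antigen; dendritic cells carry the antigen to the lymph node, where
CTL clones expand and infiltrate back; tumor cells under androgen stress
secrete CSF1 (recruiting macrophages, which secrete EGF/VEGF/IL10) and
TRAIL (expanding Tregs, which secrete WNT5A, closing a positive loop on the
tumor); and a growing fraction of tumor cells switches one-way to an
androgen-independent state that synthesizes DHT autonomously, driving the
CRPC rebound about two weeks after castration.

## Quasi-steady-state coupling of the ODE layer

With the shipped rate constants (all decay rates 0.2/min) the cascade
settles to within 5% of its fixed point in under an hour of simulated time,
while agents decide every 2 hours. The agent layer therefore evaluates each
tumor cell's proliferation fold change at the closed-form steady state
implied by its current local ligand doses (`prolif_fold_ss()`), rather than
re-integrating the ODE per cell per step. `integrate_signaling()` (a
stiff-capable `deSolve::lsoda` wrapper) remains the reference path, and the
test suite checks that the two agree.

The no-stimulation baseline of the fold change is degenerate (an
unstimulated quiescent cell has a zero readout), so a fixed basal
proliferation offset (default 0.01) is added to numerator and denominator;
the fold change is then exactly 1 at zero dose and under complete blockade.

## Parameter fitting

The signaling parameters are estimated by minimizing the L1 objective (the
sum of absolute residuals between observed and predicted protein activities
at the design points {0, 30, 60, 420} minutes, with Skp2 restricted to
30/60 min) with a real-coded genetic algorithm: tournament selection (size
3), blend (BLX-α) crossover, Gaussian mutation, one elite. Bounds default
to $k, d \in [10^{-4}, 1]$ min⁻¹ and $H \in [10^{-3}, 10]$. Because no
public protein time-course table accompanies the model,
`generate_synthetic_observations()` is a first-class synthetic-data module:
it simulates a known parameter set under WNT5A-only and EGF-only
stimulation and adds Gaussian noise clipped at zero. Parameter-recovery
tests assert *trajectory* recovery (within 5% RMS at the design points);
the parameter vector itself is not identifiable from 13 observations and is
not asserted.

## Study conditions and desk-scale geometry

The default configuration is the package's calibrated study condition: 200
tumor cells, 100 macrophages, 2 CTLs and 2 Tregs seeded at time zero;
castration at week 4; a 9-week horizon; a census recorded every 2 hours;
and 20 replicates per arm. The tumor occupies a 50×50×50 lattice at 80 µm
spacing (a 4 mm cube) joined to a 24³ lymph-node box by a lymphatic-vessel
conduit; the y = 1 face of the tumor cube is the parent blood vessel. The
200 seeded cells are dispersed in a ~1 mm-radius ball, so the initial
lesion sits just below the ~2 mm-diameter angiogenesis threshold and
crosses it during early growth. Castration fires on the week-4 clock: at
this desk scale the lesion cannot literally reach a 4 mm radius, so tumor
size in millimetres is a derived diagnostic, not an event trigger.

Numerical choices: the explicit diffusion scheme substeps automatically to
respect $D\,\Delta t/h^2 \le 1/6$; the engine accumulates secretion every
step and applies the diffusion pass on alternate steps with the doubled
(still stable) step, which leaves the quasi-steady field profiles unchanged
at half the stencil cost; androgen relaxes exponentially (time constant 48
h) to 10% (blood) and 20% (tissue) of baseline rather than stepping, so the
castration instant is continuous; cytokine fields are pre-equilibrated for
72 simulated hours under the seeded census before the clock starts, so the
initial census is not an artifact of empty fields.

## Design choices where the design was open

* **Dispersal weights.** The migration/placement rule scores each empty
  candidate site by $w_{dist} = 1/|d|$, $w_{occ} = 1/(1+\#\text{occupied
  neighbors})$ and a per-type weight (default 1); a move is accepted with
  the clamped score. Only the dependencies of the rule are prescribed by
  the model class; these specific forms are the package's choice.
  Neighborhoods are Chebyshev (26-connected), R = 2 for migration and R = 1
  for division placement.
* **Long-range T-cell homing.** Neighbor-count chemotaxis alone cannot
  steer a T cell across the ~1 mm gap between the lymphatic-vessel entry
  and the tumor, so migrating CTLs additionally weight candidate sites by
  the local concentration of a tumor-derived field (TRAIL) raised to a
  gain, and Tregs by the CTL-derived IL-2 field — a scale-free form of
  gradient climbing that reduces to the unbiased rule on flat fields.
* **Macrophage population control.** TAM recruitment/division follows a
  CSF1 Hill term (so CSF1R inhibition acts multiplicatively), plus a
  CSF1-gated monocyte influx at tumor-adjacent sites and a local crowding
  factor $(1-n/K)$ on division. The influx prevents stochastic extinction
  of a ~100-cell population; the crowding factor bounds the
  castration-induced expansion so the day-7/day-14 folds approach a finite
  plateau instead of running away.
* **Castration-responsive secretion.** Tumor-cell CSF1 and TRAIL secretion
  and macrophage IL10/VEGF secretion scale with an androgen-stress factor
  $1 - \mathrm{hill}(A)/\mathrm{hill}(1)$, encoding ADT-induced CSF1
  expression, WNT5A/CRPC-driven TRAIL, and ADT-polarized macrophage
  activation. Resistant (CRPC) tumor cells secrete TRAIL at an amplified
  rate, which is what drives the late regulatory-T-cell expansion.
* **Resistance switching.** The per-step probability of the one-way switch
  to androgen independence ramps linearly over two weeks to a plateau
  (default 0.005/step). Under castrate survival conditions this makes the
  surviving cohort majority-resistant at a median of ~15 days, matching the
  model's two-week AR-reactivation claim; resistant cells sense
  `max(tissue androgen, a_auto)` — autonomous DHT synthesis — and
  collectively pull the global tissue androgen back up toward a plateau.
* **Treg activation.** CTL activation in the lymph node is
  antigen-load-driven (saturating in the number of stimulating dendritic
  cells); Treg activation is DC-gated but rate-constant, so the
  post-castration lymph-node Treg rise is carried by IL-2-driven
  proliferation. This is what makes full IL-2 neutralization flatten the
  lymph-node Treg trajectory, as the model class requires.
* **Sensitivity-scan output.** The one-at-a-time ±5% scan reports the
  percent change of the model's standard endpoint — the mean tumor-cell
  fold change at 5 weeks post-castration relative to the pre-castration
  census — under shared replicate seeds. The fold change (not the raw
  count) is the quantity every other output of the model is reported in.
* **IL10's target.** IL10 suppresses CTL killing (not proliferation); the
  alternative is reachable through configuration by adding the same Hill
  term to the death rate, but is off by default.
* **SD convention.** All replicate spreads are sample standard deviations
  (n − 1).

## What the synthetic data does and does not show

The synthetic-observation generator emulates normalized protein time
courses sampled at four design points with additive Gaussian noise; it does
not emulate blot-to-blot normalization artifacts, detection floors, or
correlated measurement error. Passing the recovery tests therefore shows
that the fitting machinery works on data of the assumed form, not that the
experimental design identifies the parameter vector. Similarly, the
agent-based model's calibration targets are population fold changes; the
defaults reproduce those aggregate trajectories at desk scale (50³ lattice,
20 replicates) and make no claim about single-cell-resolved spatial
statistics.

## Known limitations

* Replicate-to-replicate variance of the small tumor-resident T-cell
  census is large (initial 2 + 2 cells; clonal bursts of 2⁷–2¹⁰), so the
  CTL and Treg fold changes carry wide spreads, as the model class itself
  reports. The regulatory-T-cell fold at 5 weeks is the most variable
  output and its replicate mean can fall below the published value.
* No oxygen/nutrient field: vascularization acts directly as a
  perivascular proliferation bonus.
* Drug efficacies are constant fractions (no pharmacokinetics); dosing
  regimens beyond complete blockade are configuration, not biology.
* Androgen is two well-mixed scalars, not a spatial field.
* Blood flow, vessel pruning and vascular metastasis are out of scope.
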