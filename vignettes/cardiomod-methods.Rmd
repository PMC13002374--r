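---
title: "Modeling inflammatory electrophysiological remodeling in cardiac tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inflammatory electrophysiological remodeling in cardiac tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`cardiomod` simulates two-dimensional cardiac tissue electrophysiology with
the monodomain reaction–diffusion model

$$\frac{\partial V_m}{\partial t} \;=\; -I_{ion}(V_m, \mathbf{y}) + I_{stim}
\;+\; \nabla \cdot \big( D(\mathbf{x})\, \nabla V_m \big),$$

where $V_m$ is the transmembrane voltage (mV), $\mathbf{y}$ the vector of
gating variables and intracellular concentrations, $I_{ion}$ the total ionic
current of the cell model (A/F, numerically equal to mV/ms on $V_m$), and
$D$ a per-element scalar diffusivity (cm²/ms) proportional to tissue
conductivity. The motivating science is inflammation-driven atrial
arrhythmogenesis: pro-inflammatory (M1) macrophage activation downregulates
*SCN5A* (the Nav1.5 channel carrying $I_{Na}$), *ATP1A1* (the Na⁺/K⁺
ATPase carrying $I_{NaK}$) and *GJA5* (connexin 40, i.e. intercellular
conductivity) in atrial cardiomyocytes. The package represents those three
axes as multiplicative scalers — $s_{Na}$ and $s_{NaK}$ on the two currents
and $s_{cond}$ on the local diffusivity — applied inside circular tissue
patches, so remodeled and control myocardium coexist in one sheet, and asks
which combinations destabilize the beat.

Two cell models are built in, transcribed from their original published
equation sets and accessible through one interface:

* `"hipsc"` — the spontaneously beating human induced pluripotent stem cell
  derived cardiomyocyte model of Paci, Hyttinen, Aalto-Setälä & Severi
  (2013), in its ventricular-like spontaneous variant (18 state variables,
  including the funny current $I_f$ responsible for automaticity). We chose
  the ventricular-like variant because it is the standard spontaneous
  variant of that model family; the state vector, gates and conductances
  are listed by `cell_initial_state("hipsc")` and in `src/model_hipsc.cpp`.
* `"atrial"` — the adult human atrial myocyte model of Courtemanche,
  Ramirez & Nattel (1998) (21 state variables), quiescent without stimulus.

Hallmark behaviors are enforced by the test suite: the hiPSC model beats
spontaneously at ~37 min⁻¹ with a maximum diastolic potential of −77 mV,
peak +28 mV, maximal upstroke ~24 V/s and APD90 ≈ 480 ms; the atrial model
rests at −81 mV and produces a paced action potential with ~180 V/s
upstroke and APD90 ≈ 290 ms. A further test integrates the identical
right-hand side with `deSolve::lsoda` (adaptive step, independent of the
package's fixed-step integrator) and requires the spontaneous rate to agree
within 1%.

## Numerical scheme

**Reaction.** Hodgkin–Huxley gates advance by the Rush–Larsen scheme
(exact exponential relaxation toward the voltage-dependent steady state);
voltage and concentrations advance by forward Euler. Voltage-dependent
steady states, rate factors and current coefficients are pre-tabulated on a
0.05 mV grid over [−150, 100] mV and linearly interpolated; the table rows
are interleaved so one voltage lookup touches two adjacent memory rows.
Table accuracy is second-order in the grid spacing and does not limit the
dt-convergence checks below.

**Slow cache.** Quantities that drift on millisecond scales are refreshed
at a coarser cadence than the reaction step: calcium-dependent gate targets
(τ ≈ 2 ms) roughly every 0.1 ms, Nernst potentials and slow rate factors
(intracellular Na⁺/K⁺ drift over seconds) roughly every 1 ms. The
dt-convergence test (below) is run with this cadence in place, so the
approximation is covered by the verified error bound.

**Diffusion.** Godunov operator splitting: per macro step the reaction is
advanced, then an explicit 5-point Laplacian with no-flux boundaries. The
interface diffusivity between neighboring elements is the harmonic mean of
the two element values, which preserves flux continuity across the sharp
conductivity jumps at patch borders and makes the discrete operator
symmetric — total voltage content is conserved under no-flux boundaries to
machine precision (tested). Within each splitting interval the explicit
update is applied in sub-sweeps small enough that $D\,\Delta t/\Delta x^2
\le 1/8$ per sweep: the stability bound (1/4) still admits sign-oscillating
decay of checkerboard modes, which we observed as spurious
threshold-crossing blips near sharp stimulus gradients; the 1/8 sub-sweep
regime is monotone. Elements with negative diffusivity are non-tissue (the
pseudo-atria septum): excluded from the reaction and treated as zero-flux
walls.

**Time steps.** Single-cell default reaction dt: 0.02 ms for both models
(the dt-halving convergence bound below holds there). Tissue runs cap the
hiPSC reaction step at 0.05 ms — the cell model's slow upstroke tolerates
it — but in practice the diffusion stability (CFL) bound
$\Delta t \le \Delta x^2 / (4 D_{max})$ binds first: the diffusion step
must be an integer multiple of the reaction step and satisfy that bound
(violations error with the admissible step), and when the caller leaves
the steps unset `run_tissue()` lowers the reaction step on a 2 µs quantum
to sit at it — dt = 0.036 ms at the calibrated hiPSC diffusivity and
250 µm elements. Convergence is tested directly: halving dt changes a
10 s single-cell trace by < 0.5 mV RMS for both models, and halving dx
changes the measured planar conduction velocity by < 10%.

**Gate safety.** Rush–Larsen updates are convex combinations and cannot
leave [0,1] for in-range steady states; gates are nevertheless clamped to
[0,1] after every update and the (expected-zero) clamp count is reported in
the diagnostics. Intracellular calcium is floored at 10⁻⁹ mM to keep
Nernst potentials defined in degenerate states. An integration blow-up
(|V_m| > 200 mV) aborts a single-cell run with the failure time and returns
a flagged partial result from a tissue run.

## Conductivity calibration

Tissue conductivity is not taken from literature values; it is calibrated
so that a planar wavefront in control tissue propagates at the target
conduction velocity — 45 cm/s for the hiPSC sheet and 0.8 m/s for the
atrial body. `calibrate_conductivity()` brackets the diffusivity with the
cable-theory square-root law ($CV \propto \sqrt D$) and bisects on log-D
until the *independently measured* velocity is within tolerance (default
2%). Measurement happens on a 5 cm single-element-wide cable (200 × 250 µm
elements): all elements start from the settled single-cell state, a single
wave is triggered by edge stimulation, and CV is the probe distance over
the activation-time difference between the 25% and 75% probes — the middle
half of the cable, which keeps one full centimeter away from either end and
thus outside boundary/stimulus artifacts.

The spontaneous hiPSC model needs care here: the settled state is
snapshot at the maximum diastolic potential (the most excitable phase,
farthest from the next spontaneous upstroke), so the triggered wave
finishes its ~120 ms transit long before intrinsic automaticity fires.
Checkpoints at 10/25/50/75/90% of the cable must activate in strictly
increasing order; a spontaneous focus breaks that ordering and invalidates
the measurement. The calibrated control values are stored as the package
defaults (hiPSC: 4.157 × 10⁻³ cm²/ms; atrial: 2.492 × 10⁻³ cm²/ms) and the
round trip — calibrate, then re-measure — is an acceptance test.

## Remodeling patches

`place_circular_patches()` draws circle centers uniformly over the target
region by rejection sampling: a candidate is accepted when its center is at
least one diameter from every accepted center (patches never overlap) and
the updated coverage does not overshoot the target band. Patches may
overlap the region boundary and are clipped; coverage is the exact count of
region elements whose centers fall inside a patch, divided by the region
size. Placement stops within ±2 coverage points of the target (the paper's
"half of the cells" convention makes exact 50% unattainable with
fixed-radius circles) and fails loudly, reporting the best achieved
coverage, when geometry makes the target unreachable. A seed is mandatory;
placement is deterministic given the seed, and the generators save and
restore the session RNG state.

Scenario grids are enumerated rather than hand-listed:
`enumerate_hipsc_scenarios()` yields control plus the three single-axis
downregulations ($I_{Na}$, $I_{NaK}$, conductivity) and the three pairwise
combinations, at 25% and 50% intensity (13 rows);
`enumerate_atria_configs()` yields the Cartesian product of
{control, localized-venous, spread} over the two atria minus the
all-control cell — eight remodeled configurations plus the control mesh,
each remodeled patch carrying 50% $I_{NaK}$ and conductivity reduction at
0.5 cm radius.

## Desk-scale study conditions

The full-size experiments (a 6.25 cm² hiPSC sheet observed for 50 s; a
half-million-element three-dimensional atrial mesh) are reduced to sizes a
single CPU handles in minutes, with the following reasoning:

* **hiPSC mechanism runs:** 40 × 40 elements of 250 µm (1 cm²), 20 s of
  spontaneous activity, three patch seeds per scenario. Twenty seconds
  covers ~12 spontaneous beats, enough for a per-element rate CV.
* **Patch radius on the reduced sheet: 0.5 cm — the full-size value.**
  Patch radius is an *absolute* length: what matters physically is its
  ratio to the electrotonic space constant, not to the sheet size, and
  sub-0.35 cm patches behave qualitatively differently (the full-size
  protocol reports cessation effects for 0.25–0.34 cm patches and optimal
  effects at 0.5 cm; a purely geometric rescale to 0.2 cm indeed shows no
  combined-downregulation effect here). Half coverage with a 0.5 cm circle
  on a 1 cm² sheet is only reachable with a boundary-clipped patch, which
  the placement algorithm finds via seeded restarts.
* **Pseudo-atria:** the whole-organ model is reduced to an idealized 2D
  two-chamber sheet (default 4 × 2.5 cm at 500 µm; tests use 3 × 2 cm):
  two rectangular chambers separated by a non-conducting septum, joined by
  a conducting interatrial bridge, with venous sub-zones along the
  superior border and a sinus-node pacing site on the superior right
  atrial border. This preserves what the patch logic needs — two chambers,
  venous vs. spread placement, sinus pacing — and abandons realistic
  anatomy, fiber orientation and regional heterogeneity, which are out of
  scope. Venous-localized patch placement targets ~45% of the venous band
  with a ±10-point band, because a 0.5 cm patch diameter exceeds the band
  height and clipped coverage is coarse-grained.
* **Stress pacing:** 10 sinus beats at 85 min⁻¹ (cycle length 700 ms)
  then 5 beats at 190 min⁻¹ (310 ms), the stress train starting one
  310 ms cycle after the last sinus pulse ("subsequently" is not more
  precise than that; the composition rule is a package decision). The
  scaled control-quiescence test uses 4 sinus beats — capture is periodic,
  so later sinus beats add no information.

## Readout statistics

**Beat irregularity** is the coefficient of variation of the beat rate in
percent: rates are instantaneous per-interval rates $60000/\Delta t_{ms}$,
and irregularity $= 100 \cdot SD(rate)/\overline{rate}$, zero exactly when
all intervals are equal and invariant to a global time rescaling. The SD is
the sample SD by default (`sd_mode = "population"` available). At tissue
level the statistic is computed per element from its activation series and
aggregated by the median across elements (mean available; per-element
values are returned). Activations are upward threshold crossings, linearly
interpolated, with a refractory debounce (100 ms hiPSC, 50 ms atrial) and
a 10 mV Schmitt-trigger hysteresis that suppresses ripple double-counts at
the crossing level. The hiPSC threshold is 0 mV (the stated registration
rule); the atrial tissue default is −60 mV, because the propagating
adult-atrial upstroke overshoots only a few mV under desk-scale
discretization while its foot crosses −60 mV briskly in both directions.
The median was chosen because a minority of wave-break-adjacent elements
can carry extreme CVs; the source does not state its aggregation, so this
is a declared package decision.

**Conduction fields** come from central finite differences on the
activation-time surface of one beat: with $\mathbf g = \nabla T$ (ms/cm),
velocity is $\mathbf g / |\mathbf g|^2$ and the conduction direction the
unit vector $\mathbf g/|\mathbf g|$. Elements with $|\mathbf g|$ below 1
ms/cm (speeds above 10 m/s — effectively simultaneous activation) are
invalid. The **heterogeneity index** is the circular variance of the
direction field, $1 - |\,\overline{\mathbf u}\,|$: 0 for aligned vectors,
1 for balanced disorder; a local mode averages the circular variance over
3 × 3 neighborhoods. The exact formulas behind the original heterogeneity
and conduction-velocity mapping references are not restated in the source
text; these implementations are declared substitutes with the stated
properties (closed-form value $1 - I_1(\kappa)/I_0(\kappa)$ under von
Mises directions, tested at κ = 4).

**AP morphology**: per beat, amplitude = peak − preceding diastolic
minimum; APD90 runs from the activation time (maximal dV/dt) to 90%
repolarization of the amplitude; AUC90 integrates $V - V_{90}$ over that
window; across-beat variability is SD/mean × 100 — the alternans-sensitive
statistic. Unrepolarized final APs are dropped with a warning.

**Sustained (fibrillation-like) activity**: a run is classified sustained
when ≥ 25% of elements register ≥ 2 activations after the last stimulus
plus a 50 ms blanking window, within a 2 s observation window. These
thresholds are package definitions — the source describes induced
fibrillation qualitatively — and are deliberately conservative about
boundary re-excitation: a fully captured control run scores 0.

## Synthetic readouts

The generators in `gen_*` emulate the study's readouts with known ground
truth, so every analysis statistic is testable without tissue simulation:
gamma-distributed inter-beat intervals (shape $1/cv^2$ — positive support
without truncation bias) for beat series; analytic activation surfaces
(planar, focal, two-source collision, and a rotor-like post-pacing phase
map) with optional Gaussian timing jitter clipped to preserve per-element
monotonicity; stylized action potentials (linear upstroke, raised-cosine
repolarization whose span is solved so APD90 equals the requested value
exactly, optional alternans); and von Mises-distributed conduction
directions (Best–Fisher sampler). They emulate event timing and waveform
shape, not raw optical/electrode physics: passing the recovery tests says
the statistics are implemented correctly, not that the simulator reproduces
any particular wet-lab recording.

## What the mechanism reproduction does — and does not — show

The headline in-silico claim is direction-only: on the patchy hiPSC sheet,
combined 50% downregulation of $I_{NaK}$ and conductivity should raise the
median tissue irregularity above control and above every single-axis 50%
scenario. The test suite runs that comparison exactly as stated (40 × 40
sheet, 20 s, three patch seeds, package defaults), computing every number
at run time — and in this implementation the comparison **fails**, a result
we report rather than hide. What the simulations show:

* Every desk-scale scenario — the combined one included — entrains into a
  regular rhythm (per-element rate CVs of order 0.1% or less).
  Pump-downregulated patches beat marginally slower in isolation and are
  captured by the surrounding control tissue; conductivity reduction
  alone leaves beat timing untouched; sodium reduction slows the tissue
  rate without destabilizing it.
* The same holds in exploratory runs at the full 6.25 cm² scale with five
  0.5 cm patches and 50 s recordings: the combined scenario stays fully
  entrained, every element beating once per tissue-wide cycle.
* This is a hard-won negative: before the diffusion operator was forced
  into its monotone regime and detection gained hysteresis, the
  sign-oscillating voltage ripples of the marginal explicit operator both
  faked threshold crossings and seeded spurious ectopy, mimicking exactly
  the patch-escape irregularity one expects from the mechanism. Treat any
  reaction–diffusion "arrhythmia" observed near the CFL limit with
  suspicion.

Plausible reasons the selectivity seen in larger published models is
absent here, in decreasing order of suspicion: the cell-model variant
(the ventricular-like spontaneous 2013 model; an atrial-like variant's
automaticity responds differently to pump inhibition), unstated details
of the original tissue implementation (initialization, solver, exact
conductivity handling, aggregation of per-element irregularity), and the
idealized 2D isotropic reduction itself. The mechanism's ingredients —
pump downregulation depolarizing the maximum diastolic potential (tested
at single-cell level), patch-border electrotonic interaction, and
conduction-dependent coupling — are all present; their
combination-specific synergy is not emergent in this configuration.

## Known limitations

* The hiPSC variant choice (ventricular-like 2013 spontaneous model) is a
  declared decision; an atrial-like variant would shift rates and APDs.
* Isotropic conductivity; no fiber orientation, no bidomain effects, no
  realistic atrial anatomy. The pseudo-atria are a topological, not
  anatomical, reduction.
* The scaled sheet supports at most a handful of competing wavefronts;
  rotor statistics, dominant-frequency analysis and phase-singularity
  tracking are out of scope.
* Calcium-subsystem stiffness is handled by the slow-cache cadence rather
  than an implicit solver; the convergence tests bound the cost of that
  choice at the default steps, not for arbitrary parameter excursions.
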