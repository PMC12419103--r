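---
title: "Methods: Circle-of-Willis hemodynamics and Doppler agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Circle-of-Willis hemodynamics and Doppler agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

`cowflow` implements a steady, patient-specific model of cerebral blood flow
in the Circle of Willis (CoW) together with the statistical machinery used to
validate simulated intracranial velocities against transcranial color-coded
duplex sonography (TCCD). Because clinical imaging and ultrasound data are
not redistributable, the package ships a synthetic-cohort generator that
emulates a consecutive minor-stroke/TIA population, so the entire validation
pipeline — simulate, "measure", compare — runs end to end on synthetic
patients. This vignette documents the models, the numerical choices, and the
limits of what the synthetic pipeline can demonstrate.

## Blood rheology

Blood is an incompressible Casson fluid: a yield-stress, shear-thinning
material with effective viscosity

$$\mu_{\mathrm{eff}}(\dot\gamma)
  = \left(\sqrt{\eta_c} + \sqrt{\tau_c/\dot\gamma}\right)^2,$$

with plastic viscosity $\eta_c = 0.0035$ Pa s, yield stress
$\tau_c = 0.004$ Pa and density $\rho = 1060$ kg/m$^3$ as defaults
(`casson_fluid()`). At high shear $\mu_{\mathrm{eff}} \to \eta_c$; at low
shear the viscosity diverges, which is the continuum expression of the
central plug in pipe flow. Two numerical choices matter:

* **Shear-rate regularization.** Evaluating $\mu_{\mathrm{eff}}$ inside a
  plug would divide by zero, so shear rates are clamped at a floor
  `gamma_floor` ($10^{-6}$ s$^{-1}$ by default, configurable). This is the
  standard bi-viscosity-style regularization of yield-stress models; at the
  floor the effective viscosity is large but finite (about $4\times10^3$
  Pa s with the default constants), which is what makes plugs numerically
  rigid.
* **Units.** Everything internal is strict SI. Velocities appear in cm/s and
  pressures in mmHg only at the clinical reporting boundary (`ms_to_cms()`,
  `mmhg_to_pa()` and friends), because the clinical literature mixes both.

For a rigid straight tube of radius $R$ under gradient $G$, the classical
closed forms apply: wall shear stress $\tau_w = GR/2$, plug radius
$r_p = 2\tau_c/G$, and flow rate
$Q = \frac{\pi R^4 G}{8\eta_c}\left[1 - \tfrac{16}{7}\sqrt{\xi}
+ \tfrac{4}{3}\xi - \tfrac{1}{21}\xi^4\right]$ with $\xi = \tau_c/\tau_w$;
below yield ($\tau_w \le \tau_c$) nothing moves. `casson_pipe_flow()`,
`casson_velocity_profile()` and `peak_to_mean_ratio()` expose these, and the
test suite closes the loop against independent quadrature and
ODE-integration oracles (0.1 % tolerances).

**Inversion.** The solvers need $G(Q)$ and $G(u_{\mathrm{peak}})$. Both
$Q(G)$ and $u_{\mathrm{peak}}(G)$ are strictly increasing and continuous
above yield, so `invert_flow_to_gradient()` and `invert_peak_to_gradient()`
use bracketed bisection in $\log G$ (globally convergent, relative
tolerance $10^{-10}$). Zero flow returns the yield gradient $2\tau_c/R$ by
convention — any smaller gradient is equally valid, and this choice makes
the inverse continuous from above.

## The two solver tiers

The package deliberately has two tiers that are verified against each other.

### Finite-volume segment solver

`solve_segment()` solves the steady incompressible momentum and continuity
equations in one axisymmetric vessel segment on a uniform staggered
(r, z) grid, with the Casson viscosity evaluated per cell from the local
shear-rate invariant. The iteration is a SIMPLE-family pressure-correction
scheme: an optional implicit momentum predictor, a pressure-correction
equation enforcing per-cell continuity, an explicit velocity correction, and
one or more corrector loops per outer iteration. Steady state is reached by
iterating with under-relaxation (velocity 0.7, pressure 0.3 by default);
the under-relaxation plays the role of large pseudo-time steps, so the
transient term has no physical time accuracy — only the converged steady
state is meaningful.

Numerical choices, all configurable through `solver_settings()`:

* Convection is first-order upwind; the Reynolds numbers of CoW segments at
  desk scale are modest and the verification cases are dominated by radial
  diffusion, where the discretization is second order.
* The viscous term is implemented in $\nabla\cdot(\mu\nabla u)$ form; the
  axial transpose-stress contribution
  $\nabla\cdot(\mu(\nabla \mathbf{V})^T)_z$ is added as an explicit deferred
  source. It vanishes identically in developed flow. The radial-momentum
  transpose remainder is neglected (it also vanishes in developed
  axisymmetric flow); this is a documented simplification.
* The shear-dependent viscosity is Picard-lagged one outer iteration with
  relaxation 0.7 — standard practice for generalized Newtonian fluids.
* Global mass conservation is enforced exactly every iteration by scaling
  the outlet velocity to the prescribed inlet flow; convergence is declared
  when the normalized per-cell mass residual and the momentum residual both
  fall below $10^{-6}$.
* Boundary conditions: velocity inlet (flat or analytic Casson profile),
  uniform pressure outlet (the pressure level is anchored at the outlet
  face; it does not influence the velocity field), rigid no-slip walls via
  half-cell wall conductances. Without the momentum predictor a single
  explicit Jacobi sweep of the assembled momentum system is used instead —
  slower, but it converges to the same state.
* Tapered or stenosed radius profiles are represented by blocked (solid)
  cells on the uniform grid (staircase walls). Quantitative accuracy claims
  are made only for straight tubes, where the analytic solution exists; the
  staircase cases are smoke-tested for convergence and conservation.

Verification: with the analytic Casson profile imposed at the inlet, the
developed numerical profile at 90 % of the length matches the closed form
within 2 % (radius-weighted L2) already at $16\times64$ cells and within
about 0.01 % at $32\times256$; the axial pressure gradient matches the
inverted pipe law within 3 %; the grid-convergence study
(`grid_convergence_study()`) shows monotonically decreasing error under
refinement. These are exactly the checks in `tests/testthat/`.

### Reduced-order network solver

`solve_network()` treats the CoW as a graph of cylindrical segments, each
obeying the closed-form Casson pipe law, with Kirchhoff mass balance at
junctions. Inlets (both internal carotid and both vertebral arteries) carry
the volumetric flow implied by their Doppler envelope peak velocity — the
gradient whose Casson profile has that centreline velocity is found per
inlet, so the peak-to-mean conversion is self-consistent rather than a fixed
factor. Outlets carry a uniform pressure. Unknown junction pressures solve
the nonlinear nodal system by damped Newton (step halving on residual
increase, up to 30 halvings), started from the Newtonian linear-network
solution, which is exact when $\tau_c = 0$ and an excellent predictor
otherwise; typical solves need a handful of iterations to a mass-balance
residual of $10^{-9}$ of total inflow. Below-yield segments have zero
flow and a singular local Jacobian; a small conductance floor keeps the
Newton matrix regular without altering the converged solution.

Design choices worth stating:

* **Phases.** A steady solver cannot produce a waveform, so the three
  clinical velocities come from three independent steady solves: the PSV
  solve uses the patients' peak-systolic inlet velocities and systolic
  outlet pressure, EDV diastolic, MFV mean arterial pressure. With uniform
  outlet pressures the pressure level does not redistribute flow, so the
  phase distinction lives entirely in the inlet velocities; this is the
  only phase mapping consistent with steady physics.
* **Reported velocities** are centreline (plug) velocities of the segment's
  Casson profile, i.e. the quantity a Doppler envelope measures, read at
  the conventional insonation segments (M1, A1, P1, BA, V4; midpoint —
  along a uniform segment the profile is axially constant). Flow volumes in
  mL/min are taken from the mean-flow (MFV) solve.
* **No distal vasculature.** Only CoW anatomy is modelled — no
  microvascular outflow impedances, no autoregulation, no junction minor
  losses. Flow therefore splits by the resistance of the large-artery
  segments alone, which biases absolute velocities above typical clinical
  TCCD values (the short, wide M1 attracts proportionally more flow than a
  real MCA territory does). This affects absolute magnitudes, not the
  structure of the validation statistics, because both the "simulated" and
  the "measured" member of every pair derive from the same model (see
  below).

Cross-tier consistency is tested: for one straight segment the network
pressure drop and peak velocity agree with the finite-volume solution
within 3 %.

## Synthetic anatomy

`build_cow_template()` constructs the canonical CoW graph — 2 ICA + 2 VA
inlets, basilar trunk from the vertebral confluence, the M1/A1/P1 ring with
the anterior and both posterior communicating arteries, six outlets
(terminal MCA, A2, P2 bilaterally) — from an editable geometry table of
literature-typical radii and lengths (`cow_geometry_defaults()`); no
imaging is needed. Anatomical variants are first-class: presence flags
delete communicating arteries, hypoplasia factors in (0, 1] shrink A1/P1
and the carotids, and `build_cow_template()` refuses a variant that
disconnects an outlet, naming the orphan. An optional pair of superior
cerebellar outlets off the distal basilar artery exists but is off by
default — their status in the outlet set is anatomically ambiguous, and the
posterior validation sites (BA, V4, P1) do not need them.
`perturb_geometry()` adds reproducible lognormal inter-patient variability
(default log-SD 0.08) on radii and lengths. Networks serialize to a
versioned JSON schema with exact round-tripping.

The network is purely topological (lengths and radii, no 3D embedding):
nothing in a reduced-order or developed-flow model uses curvature, and
keeping it topological is what makes 10,000-patient cohorts instantaneous.

## The synthetic cohort and the measurement model

`generate_cohort()` draws, per patient: age (62.4 ± 15.2 y), systolic and
diastolic pressure before the ultrasound examination (133.7 ± 21.0 /
80.3 ± 14.7 mmHg; ordering enforced by resampling the pair, MAP =
DBP + (SBP − DBP)/3), per-side ICA and VA peak-systolic inlet velocities
(60.1 ± 17.4 and 41.6 ± 17.5 cm/s), an anatomical variant, and a geometry
seed. Three choices deserve explanation:

* **Floored velocities with moment matching.** Inlet PSVs are sampled from
  normals truncated below (ICA at 15, VA at 10 cm/s) so no patient has a
  non-physiological inlet. Naive truncation of N(41.6, 17.5²) at 10 would
  bias the mean upward by 1.4 cm/s and shrink the SD by ~8 %, so the
  underlying parameters are numerically adjusted
  (`truncnorm_match_moments()`) so that the *truncated* distribution has
  exactly the stated mean and SD. The cohort therefore recovers its target
  moments within Monte-Carlo error at any n, which is the property the
  acceptance checks exercise at n = 10,000.
* **Triplets from PSV.** Clinical cohort tables report inlet PSV only. EDV
  is modelled as a fraction 0.33 ± 0.05 of PSV (truncated to 0.15–0.5) and
  MFV by the standard Doppler envelope formula (PSV + 2·EDV)/3 — both
  conventional sonographic relations, both configurable. Sides are drawn
  independently; a patient-level correlation between sides would sharpen
  left/right contrasts but affects none of the statistics computed here.
* **Variant prevalences** default to textbook figures (absent AComm 5 %,
  absent PComm 25 % per side, A1 hypoplasia 10 %, P1 hypoplasia 15 %,
  factors uniform on 0.4–0.7). Carotid narrowing defaults to none because
  the emulated population explicitly excludes large-artery disease.

`synthesize_tccd()` is the measurement model: one multiplicative Gaussian
factor (SD 0.15 by default) scales a site's whole PSV/EDV/MFV triplet —
Doppler gain and sample-volume placement errors mis-scale the entire
envelope, hence the shared draw — and, with per-artery probability, the
site is "measured without angle correction", multiplying the triplet by
$\cos\theta$ with $\theta$ uniform on (0°, 30°). The per-artery
probabilities default to clinical practice frequencies (MCA ~32 %
uncorrected, ACA/PCA 40 %, BA 87 %, V4 70 %), which reproduces the
qualitative clinical signature: posterior-circulation velocities are
systematically underestimated by ultrasound relative to simulation. The
per-phase error correlation within a site is an assumption (the true
correlation structure of TCCD error is not identifiable from published
summaries); it is the conservative choice for agreement statistics because
it preserves the triplet's internal ordering.

`run_virtual_study()` chains everything: cohort → per-patient network and
boundary conditions → three-phase simulation (the "simulation" arm) → the
same true values through the measurement model (the "TCCD" arm) → a long
paired table. Failures are logged and excluded with a count (none occur
under defaults). Everything is a pure function of (n, seed, parameters).

**What passing this pipeline does and does not show.** Noise-free mode
proving ICC = 1 and zero differences, and noise monotonically degrading
ICC, validate the *statistical machinery and its wiring*, not the clinical
fidelity of the simulator: in the virtual study the measured arm is
constructed from the simulated arm, so agreement is true by design and only
its degradation under the noise model is informative. Real-data features
the synthetic pipeline does not emulate include inter-sonographer
variability, insufficient temporal bone windows, distal runoff physiology,
and disease effects on vessel mechanics.

## Agreement statistics

`build_report()` produces the full per-artery validation table for the nine
sites (MCA, ACA, PCA, V4 left/right and BA) and three velocity types.

* **ICC** (`icc_absolute_agreement()`): two-way, absolute-agreement, single
  measures, from the ANOVA mean squares with $k = 2$ methods —
  $(MS_R - MS_E)/(MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E))$ — with the
  standard two-way CI and the F-test of the subject effect ($MS_R/MS_E$)
  as the p-value. The implementation is checked to $10^{-10}$ against an
  independent `aov()` decomposition on random tables, and to $10^{-12}$
  against an external reference on a frozen hand table. Labels follow the
  conventional thresholds (0.5/0.75/0.9 for moderate/good/excellent) via
  `icc_interpret()`.
* **Differences** (`difference_row()`): measured minus simulated, with the
  percent difference taken relative to the *simulation* mean. The published
  reference table shipped with the package
  (`reference_agreement_table()`) pins this convention: its BA row
  (−7.6 cm/s on a simulation mean of 57.8) prints −13.1 %, which only the
  simulation denominator reproduces. Overall rows are unweighted means over
  the nine arteries; the grand overall averages the three velocity-type
  overalls. Report cells round half away from zero to one decimal
  (`round_report()`); full precision is kept internally. A few published
  EDV/MFV rows are internally inconsistent with their own rounded means
  (they were evidently computed on unrounded data), which is why overall
  aggregation is defined over per-row values, not recomputed means.
* **Bland–Altman** (`bland_altman()`): differences are tested for
  normality by Shapiro–Wilk; if rejected at 0.05 the centre is the median
  and the limits of agreement are the 2.5th/97.5th percentiles (linear
  interpolation between order statistics — the default `quantile()`
  definition, pinned for reproducibility); otherwise mean ± 1.96 SD.
  Shapiro–Wilk decides alone because of its small-sample power; a second
  omnibus test would add nothing at n ≈ 53. Paired arteries are compared
  on the per-patient mean of left and right (`side_averaged_pairs()`),
  matching clinical practice.

## Problem sizes and defaults

The shipped verification settings are chosen to make every check an
analytic comparison at desk scale: segment verification at $16\times64$
(units) and $32\times256$ cells (reference resolution), grid-convergence
at three doublings from $8\times16$, virtual studies at n = 53 (the
emulated cohort size) and cohort calibration at n = 10,000. A full
53-patient, three-phase virtual study runs in a few seconds on one core;
the reference-resolution segment solve takes a few seconds more.

## Known limitations

* Rigid walls, steady flow: no pulsatility, no compliance, no
  fluid–structure interaction; PSV/EDV/MFV are three steady snapshots.
* No distal vascular beds or autoregulation; absolute intracranial
  velocities run high relative to clinical TCCD (see above), and flow
  splits are resistance-driven rather than demand-driven.
* The axisymmetric segment solver is a verification vehicle, not a
  patient-geometry solver; 3D unstructured meshes are out of scope.
* The TCCD error model is multiplicative and site-shared by assumption;
  dropout from insufficient bone windows is not modelled.
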