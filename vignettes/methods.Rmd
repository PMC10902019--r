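---
title: "Methods: a reduced-order Circle-of-Willis pipeline for Doppler method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order Circle-of-Willis pipeline for Doppler method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

## Scope and model overview

`cowflow` compares transcranial-Doppler (TCD) envelope velocities in the
middle cerebral artery against velocities produced by a flow-conserving
simulation driven by extracranial duplex measurements. The full-fidelity
version of this workflow runs a 3D finite-volume Navier–Stokes solver on a
patient-specific angiographic geometry; this package deliberately replaces
that solver with a **quasi-steady nonlinear Poiseuille circuit** on a
segment network, keeping everything around it (waveform processing,
boundary-condition generation, metric extraction, statistics) faithful. The
surrogate preserves the property the comparison actually exercises — mass
conservation and diameter-driven flow routing — while discarding 3D
secondary flows, developing-flow effects and pulsatile inertia.

Consequences to keep in mind:

* **No Womersley effects.** Each phase point of the cardiac cycle is an
  independent steady solve; phase lag and inertial flattening of velocity
  profiles are absent. A permutation of phase points permutes the solution
  (this is tested).
* **Parabolic profiles.** Maximal velocity is exactly twice the
  cross-sectional mean (`v_max = 2 v_mean`). Real M1 profiles are blunter,
  so the surrogate's absolute maximal velocities run higher than a 3D
  solution for the same flow; absolute levels should be interpreted through
  the method-agreement lens (biases, correlations), not as calibrated
  physiology.
* **Rigid walls, laminar flow, no-slip** — matching the standard
  cerebrovascular-CFD assumption set.

## Waveform processing

Duplex envelopes arrive as ≥ 16 samples per cardiac cycle, typically over
three cycles. Each cycle is smoothed with a cubic smoothing spline whose
smoothing parameter is picked by generalized cross-validation but **capped**:
if the smoothed curve departs from the samples by more than 1% RMS of the
signal range, the fit falls back to an interpolating periodic spline. Clean
waveforms therefore pass through essentially unchanged (the idempotence
test asserts this). Cycles are resampled to a uniform phase grid in [0, 1),
circularly shifted so each cycle's global maximum lands at the alignment
phase (default 0.25 — any consistent choice works, since every downstream
comparison is phase-consistent), averaged pointwise, and given the mean of
the input periods.

The envelope-to-flow conversion assumes Poiseuille flow. Because the Doppler
envelope is the instantaneous *peak* velocity and the parabolic-profile mean
is half the peak, `poiseuille_flow()` uses Q = ½ V_env π(D/2)² with the ½
exposed as `envelope_factor`: laboratories whose envelope already represents
an intensity-weighted mean velocity should set it to 1. The diameter is the
recording's time-averaged B-mode value and is held constant (rigid walls
downstream make a time-varying diameter meaningless here).

Negative envelope samples are rejected rather than clipped: in this
protocol all four inflow arteries and the M1 carry antegrade flow, so a
negative sample indicates a processing error, not physiology.

## Boundary conditions

Total inflow (the pointwise sum of the four artery flows) is first split
across seven cerebral territories — left/right posterior, left/right middle,
anterior, cerebellum, ophthalmic — by a regional fraction table, then within
each territory across its outlets by the Murray-type diameter-power law with
exponent n = 2.33. The regional fractions used by the original scheme are
not public, so the table is a **required input**; the package ships a
clearly-labelled provisional default (anterior 0.18, middles 0.25 each,
posteriors 0.10 each, cerebellum 0.09, ophthalmic 0.03) used by the
synthetic cohort and tests. It encodes the usual dominance of the MCA
territories and a small ophthalmic take-off; it is not a fitted quantity.
No flow-dependent adjustment of the fractions is implemented (per-condition
tables may simply be supplied), since the mapping from measured inflow to
regional fractions lives in a separate prior method.

Split fractions are computed on diameters normalised by their maximum, so
extreme exponents neither overflow nor lose scale invariance; fractions are
smooth in the diameters, so ties need no special handling. Global
conservation (outlets = inlets at every phase point, ≤ 1e−9 relative) is
asserted at construction time and independently re-verified in tests.
Boundary extrusions (11 × boundary diameter by default) are exported as
manifest metadata for external 3D solvers; the network surrogate needs no
development length, so inlet "plug flow" reduces to a prescribed nodal flow
injection.

## Network solver numerics

At each phase point the solver assembles nodal conductances
G = πD⁴/(128 μ_eff L) and solves the reduced Laplacian system (reference
node pinned to 0 Pa; the choice is arbitrary and flows are invariant to it,
which is tested). Shear-thinning enters through the effective viscosity at
the characteristic Poiseuille wall shear rate γ̇ = 8|v̄|/D — the wall value
for a parabolic profile; other conventions (e.g. 2v̄/D characteristic rates)
only shift where on the Carreau–Yasuda curve a segment sits and are noted
here for comparability.

The viscosity fixed point is solved per phase with **Steffensen (Aitken)
acceleration**: two raw fixed-point evaluations followed by a per-segment
extrapolation, clamped to [η_∞, η_0]. The raw iteration alternates around
the solution, so the extrapolation typically converges in three to six
circuit solves to the default relative tolerance of 1e−10. Two safeguards
exist for segments with near-zero flow (communicating arteries near
flow reversal), where the shear-thinning map has unbounded slope at γ̇ = 0:
the Aitken jump is skipped when its denominator is negligible, and after 40
solves the scheme falls back to a damped (0.5) plain update. Viscosity is
warm-started across phase points. Initialisation is μ = η_0 everywhere.
Non-convergence within `max_iterations` (default 200) is an error, never a
silent result.

Degenerate inputs are rejected up front: boundary flows that do not balance
globally (> 1e−9 relative), disconnected graphs, non-positive diameters or
lengths. Wall shear stress is reported signed with the segment orientation,
τ_w = 32μQ/(πD³).

The grid-convergence-index helper implements the standard
Richardson-extrapolation bookkeeping (safety factor 1.25, pass below 3%)
for users verifying an external 3D mesh; the network surrogate itself has
no spatial grid to converge.

## Metric extraction

TCD insonation of the right M1 is emulated by sampling the maximal velocity
at three stations at 25/50/75% of the M1 path length and averaging them per
phase point. In a quasi-1D network with a single uniform M1 segment the
stations coincide; the interface is retained so that subdivided (tapered)
M1 descriptions exercise the same extraction geometry as 3D constrained
planes.

Three metrics are extracted from a peak-aligned envelope: systolic (global
maximum), time-averaged (grid mean), and end-diastolic. End diastole is the
**final phase sample** of the peak-aligned cycle — the instant immediately
preceding the systolic upstroke. Because the true minimum can precede that
sample slightly, a `min_tail` option (minimum over the final 20% of the
cycle) is available; the default was chosen for determinism and closeness
to how clinical trace software marks end diastole.

Relative change is Δ% = 100 (stimulus − rest)/rest per metric, defined only
for positive rest metrics. Its key property — invariance to any
multiplicative bias applied consistently to both conditions — is what lets
two methods disagree absolutely yet agree in relative change, and is
asserted exactly in tests.

## Statistics

Differences and Bland–Altman biases are oriented **TCD − CFD** throughout
(TCD envelope velocities run higher). Paired t-tests and Pearson
correlations use the closed-form definitions and are cross-checked in tests
against the base-R implementations; Shapiro–Wilk delegates to the
established routine. Limits of agreement use the conventional 1.96
multiplier; proportional bias is the OLS slope of differences on pairwise
means (the original reporting shows trend lines without naming the
regression; OLS is the default reading). All tests are two-sided at
α = 0.05 with no multiple-testing correction by default, matching the
study-style reporting; Holm adjustment is available via `p_adjust`.
Normality failures are reported as flags and do not switch the tests to a
non-parametric fallback. Zero-variance paired differences (e.g. when the
two sources are identical by construction) are flagged `degenerate` rather
than tested.

## The synthetic cohort: what it does and does not emulate

No participant data ship with the package, so `synth_cohort()` generates
cohorts with the statistical structure the analysis assumes:

* **Flows.** Per-artery time-averaged inflows are truncated-normal draws
  from the published condition table (rest / hypercapnia / exercise means ±
  SD for LICA/RICA/LVA/RVA; resting means sum to the published tCBF of
  618.1 mL/min). A participant's deviates are correlated across conditions
  (default ρ = 0.5, a plausible mid-range value — the true between-condition
  response correlation is not reported and is exposed as configuration).
  Hypercapnia raises all means (~+40%); exercise sits near rest (+5–20%).
* **Waveform shape.** A canonical carotid-like envelope (systolic Gaussian
  pulse plus dicrotic bump) truncated to 4 Fourier harmonics, scaled to
  pulsatility (peak − min)/mean = 1.2; heart rates (hence periods) come from
  the published per-condition values. Real envelopes vary in shape between
  arteries and conditions; the generator uses one canonical shape because
  only time-averaged flows are published.
* **Anatomy.** A complete-CoW template (paired ICAs, VAs merging into the
  basilar, MCA/ACA/PCA pairs, both communicating arteries, ≥ 1 outlet per
  territory) with log-normal diameter jitter (default CV 5%). Anatomical
  variants (missing communicating segments, fetal PCA) are not generated.
* **TCD bias.** Each participant gets multiplicative bias factors (log-normal
  between participants, default CV 10%) that are **constant across
  conditions** — the mechanism behind relative-change agreement. The bias is
  interpolated across the cycle between the systolic-phase factor (default
  1.5) and the diastolic-phase factor (default 1.9), inside the reported
  ranges of TCD excess (systolic 33–73%, time-averaged 62–85%,
  end-diastolic 85–106%); the time-averaged bias is emergent rather than
  prescribed. Log-normal multiplicative measurement noise (default CV 5%)
  is added per sample.
* **Determinism.** Every draw is keyed by a hash of the master seed and a
  label path (participant/artery/condition), so sub-streams are independent
  and a cohort is bit-reproducible; ground-truth factors and drawn flows are
  stored on each participant for recovery tests.

Passing tests on this generator therefore demonstrates that the pipeline
recovers known structure (bias magnitude, absolute/relative dissociation,
flow-table calibration) from data with the assumed statistical shape. It
does not demonstrate robustness to real-data features the generator omits:
waveform-shape heterogeneity, insonation-angle drift within a session,
anatomical variants, or non-multiplicative (additive or flow-dependent)
measurement error.

## Problem sizes and numerical defaults

Defaults: 200 phase samples per cycle, viscosity tolerance 1e−10,
conservation assertions at 1e−9 relative, ensemble grids of 200 points.
The package's own replication studies (the bias-recovery Monte Carlo in the
acceptance tests) use 200 cohorts of 12 participants with 48-point phase
grids and 48-sample recorded cycles — grid-refinement spot checks show the
extracted metrics change by well under the between-participant variability
at these sizes, so the coarser grids are used for the replicate ensembles
while single-cohort analyses keep the 200-point default.

## Known limitations

* Absolute velocity levels inherit the parabolic-profile factor of 2 and a
  template anatomy; they are structurally high relative to 3D solutions and
  should only be compared within-pipeline.
* The regional outflow table is provisional; results that depend on the
  regional split (e.g. per-territory WSS) should be re-run with
  study-specific fractions.
* The quasi-steady circuit cannot represent phase lag between inflow and M1
  velocity, cycle-to-cycle memory, or collateral recruitment dynamics.
* Communicating-artery flows near zero are resolved by the damped fallback
  at reduced order of convergence; their signs at low flow are sensitive to
  diameter jitter, which is physiological but worth remembering when
  interpreting individual loop flows.
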