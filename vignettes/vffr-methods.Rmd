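---
title: "Virtual FFR from steady coronary CFD: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual FFR from steady coronary CFD: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vffrsim)
```

## The physiological question

Fractional flow reserve (FFR) is the ratio of the time-averaged pressure
distal to a coronary stenosis to the proximal (aortic) pressure under
hyperaemia; lesions with FFR at or below 0.80 are physiologically
significant and usually treated. Virtual FFR (vFFR) estimates this index
computationally from a 3D reconstruction of the diseased lumen, removing
the need for a pressure wire. `vffrsim` implements, at desk scale, the
full simulation side of such a pipeline:

1. a parametric generator of stenosed-vessel lumens (and STL import for
   externally reconstructed anatomy);
2. a body-fitted structured hexahedral mesher whose cell count is driven
   by a 1--100% *fidelity* slider;
3. a steady incompressible Navier--Stokes finite-volume solver;
4. a two-point quadratic lesion characterization coupled to a lumped
   microvascular resistance, solved for vFFR in closed form and by
   pseudo-transient iteration;
5. a benchmarking harness (accuracy metric, Bland--Altman, exact Wilcoxon
   signed rank, ANCOVA slope comparison, threshold concordance) and an
   energy/monetary cost model.

The package does not reconstruct anatomy from angiographic projections,
does not model transient or turbulent flow, and makes no claim of
patient-level validation; it reproduces the *computational experiment* --
how vFFR responds to discretization fidelity -- on synthetic vessels with
known ground truth.

## Lesion model and synthetic cohort

A vessel is a tube of reference diameter $D_0$ narrowed by a single focal
lesion. Percent diameter stenosis $p$ prescribes the throat diameter
$D_t = D_0 (1 - p/100)$; the narrowing follows a smooth cosine taper over
the lesion length, which avoids spurious flow separation at geometric
corners (no lesion shape is standard; any smooth unimodal taper would
serve). Eccentric lesions displace the lumen centre laterally by a
fraction of the local radius deficit while keeping the cross-section
circular, so cross-sectional area -- the quantity that controls the
hydraulics -- is unchanged.

The default synthetic cohort (`synthetic_cohort()`) draws 40 vessels with
stenosis uniform in [30, 90]% and reference diameter uniform in
[2.5, 4.0] mm (seed 20230421), the case mix of a typical interventional
series. Values the clinical descriptors do not constrain were fixed once
at realistic coronary dimensions: vessel length 30 mm, lesion length
uniform in [6, 14] mm, lesion centre in [12, 18] mm, axisymmetric and
straight. What the generator deliberately does *not* emulate: real lesion
morphology (asymmetry, calcified irregularity), vessel taper and
curvature, side branches, and multiple lesions. Passing tests therefore
demonstrate correct numerics and the fidelity--accuracy--duration
relationships on idealized anatomy, not morphological fidelity to any
clinical cohort.

## Meshing and the fidelity slider

`fidelity_to_cells()` maps the percentage $f$ to a target cell count
geometrically, $n(f) = n_{\min} (n_{\max}/n_{\min})^{(f-1)/99}$, so equal
slider increments multiply the budget by a constant factor; the five
canonical levels are 10, 25, 50, 75 and 100%. The module default budget is
$n_{\min} = 8\,000$ to $n_{\max} = 160\,000$ cells. This is a deliberate
desk-scale choice: the *experiment* (the fidelity sweep and its paired
statistics) is preserved while absolute resolution is far below
production meshes of $10^6$ cells and more, so absolute pressure-drop
accuracy at a given fidelity is not comparable to production solvers.

The mesher sweeps a butterfly (O--H) multi-block quadrilateral template
along the centerline: a central square block surrounded by structured
radial layers, avoiding the centreline singularity of a polar grid. Three
wall-adjacent layers are geometrically graded (ratio 1.3) as a stand-in
for boundary-layer prisms. Two numerical details matter:

* **Equal-area calibration.** The wall polygon of an inscribed template
  underestimates the circular cross-section area by up to ~10% at the
  coarsest resolutions. All template radii are scaled so the wall polygon
  area equals the circle's; the discrete duct then carries the analytic
  cross-section area and the mesh volume converges to the analytic tube
  volume (tested to <1% at full fidelity, monotonically improving across
  the five levels).
* **Determinism.** Meshing involves no randomness; identical inputs yield
  bit-identical meshes, which the tests assert. Meshing time is excluded
  from all reported durations.

## Flow model and discretization

Blood is treated as incompressible and Newtonian ($\mu$ = 3.5 mPa s,
$\rho$ = 1056 kg/m^3 -- conventional blood-analogue values, configurable)
in rigid vessels, laminar throughout. The characterization protocol fixes
a plug inlet velocity at the prescribed flow, a uniform zero-pressure
outlet, and no-slip walls.

The solver is a collocated finite-volume SIMPLE scheme with Rhie--Chow
momentum interpolation for face fluxes: implicit first-order upwind
convection with a deferred second-order upwind correction (bounded
between the adjacent cell values so the correction cannot create new
extrema), central diffusion with over-relaxed non-orthogonal correction,
Green--Gauss gradients, and Jacobi-preconditioned Krylov solvers
(BiCGStab for momentum, CG for the pressure correction). Under-relaxation
defaults to 0.5 (momentum) and 0.2 (pressure). Convergence is declared
when all normalized momentum and continuity residuals fall below `tol`
(default $10^{-5}$). After convergence one tight pressure-correction
solve updates the fluxes only ("flux closure"), so the returned face
fluxes are discretely conservative; the boundary flux imbalance is below
$10^{-6}$ of the inlet flux on every converged solution (in practice
~$10^{-13}$).

Cross-section-averaged pressure is the volume-weighted mean cell pressure
per axial layer, interpolated onto at least 64 arclength stations; all
reported pressures are gauge relative to the outlet.

### Validation against closed forms

On a straight tube the solver is checked against Hagen--Poiseuille,
$\Delta P = 8 \mu L Q / (\pi R^4)$. With the protocol's plug inlet the
*full-length* drop necessarily exceeds the closed form (the entrance
region carries an extra loss of order $\rho \bar u^2/2$, about 20% of the
viscous drop at Re 130), so the validation measures the axial gradient
over the fully developed distal window at Re ≈ 30 and agrees within 2%.
This is the standard pipe-flow validation; the full-length comparison is
not a meaningful test under a plug inlet.

Grid convergence of the translesional pressure drop is monotone once the
discretization is inside its asymptotic range (from roughly 500 cells on
these geometries); the very coarsest desk meshes approach the limit
*non-monotonically*, with a sign change of the leading error as the
cross-section template refines. The grid-convergence property is
therefore tested on a 500--5000-cell budget, and results from the
coarsest fidelities should be read as pre-asymptotic. An empirical viscous-plus-
inertial stenosis correlation (`stenosis_dp_estimate()`, Young--Tsai
form with $K_v = 32$, $K_t = 1.52$) provides an order-of-magnitude sanity
band -- the solver must land within a factor of two on moderate stenoses,
never an equality check.

### Steady flow at high throat Reynolds number

At 3 mL/s a 70--90% stenosis reaches throat Reynolds numbers of
1000--4000. Such separated jets have no stable steady laminar solution:
the SIMPLE iteration enters a self-excited limit cycle whose amplitude no
amount of under-relaxation removes (verified down to $\alpha_u = 0.15$
with first-order convection). The solver handles this deterministically,
in stages: first-order warm-up; bounded second-order correction with
snapshot/restore and automatic permanent fallback to first-order if it
destabilizes; stepwise relaxation cuts on stall; then cycle averaging --
the state is averaged over a window of the oscillation and the run
finishes from that cycle mean. The returned solution is always the
minimum-residual state visited. Its classification is honest:

* `steady` -- residuals below `tol` ($10^{-5}$);
* `quasi_steady_cycle_mean` -- the limit-cycle machinery engaged and the
  best state sits inside an engineering band (residuals below $10^{-2}$);
  recorded in `convergence_mode` and as a warning on the solution;
* otherwise the solve fails with a structured error carrying the residual
  history, and benchmark harness drops the case from paired analyses and
  lists it in `excluded` -- on the default cohort this removes a small
  number of the most severe vessels, the analogue of a benchmark
  excluding vessels its reference arm cannot analyze.

A throat Reynolds number above the configured laminar cap (default 2000)
additionally records a warning that the laminar assumption is strained.
The quasi-steady cases are also the ones whose vFFR varies most across
fidelities, which is precisely the severity--accuracy relationship the
benchmarking experiment measures; treating them as first-class (flagged)
results rather than failures preserves that signal.

## From paired solutions to vFFR

Each vessel is solved at two flows (1 and 3 mL/s). The translesional
pressure drop at the measurement point then defines the lesion's
quadratic characteristic
$$\Delta P(Q) = f\,Q + s\,Q^2,$$
with $f$ the linear (viscous) and $s$ the quadratic (inertial)
coefficient, obtained exactly from the two $(Q, \Delta P)$ pairs
(`fit_pressure_flow()`; in mmHg and mL/s, 1 mmHg = 133.322 Pa). Small
negative coefficients can arise from discretization noise on nearly
unobstructed vessels; they are flagged, not fatal.

The coronary operating point couples this characteristic to a proximal
pressure $P_a$ and a lumped distal microvascular resistance $R_{mv}$
($P_d = R_{mv} Q$):
$$s\,Q^2 + (f + R_{mv})\,Q - P_a = 0, \qquad
  \mathrm{vFFR} = \frac{P_d}{P_a} = \frac{R_{mv} Q}{P_a}.$$
Two solvers are provided and *required to agree*: the closed-form
positive root, and a pseudo-transient relaxation
$Q \leftarrow (1-\omega) Q + \omega (P_a - fQ - sQ^2)/R_{mv}$. The
agreement (to $10^{-8}$ relative over 1000 random parameter draws) is the
correctness contract for the coupling. The plain fixed-point map is
unstable when $(f + 2 s Q)/R_{mv}$ is large, so the iteration carries
pseudo-time-step control: if an update grows, the internal relaxation is
halved (the fixed point is unchanged). Defaults $P_a$ = 100 mmHg and
$R_{mv}$ = 25 mmHg/(mL/s) put a mid-range 60% lesion near the clinical
decision zone (vFFR ≈ 0.73 on the shipped fixtures); both are labelled
conventions, not personalized physiology.

`vffr_profile()` fits the characteristic *per arclength station*, giving
a pullback-style curve with vFFR = 1 at the inlet; the headline value is
read 10 mm distal to the lesion end (configurable), standing in for the
operator-chosen measurement point. One physical caveat: steady laminar
flow partially recovers static pressure downstream of the throat, so the
station-wise profile *rises* across the recovery zone before resuming
its viscous decline. The tested invariants are therefore piecewise:
non-increasing proximal to the throat, non-increasing distal of jet
reattachment, and no recovery above the pre-lesion value. A blanket
monotone-profile claim would contradict the same model that produces the
pressure-recovery region.

## The benchmarking harness

`fidelity_sweep()` solves every cohort vessel at the five canonical
fidelities plus a reference arm -- the same solver on a mesh with twice
the 100%-fidelity cell target -- preserving the paired design. Accuracy
of a fidelity arm against the reference is
$(1 - |\mathrm{vFFR} - \mathrm{vFFR}_{ref}|/\mathrm{vFFR}_{ref}) \times 100$.
`sweep_summary()` emits per-fidelity median/IQR durations and accuracies
(type-7 quantiles), paired Wilcoxon signed-rank tests between adjacent
fidelities, Bland--Altman bias and 95% limits of agreement
($\bar d \pm 1.96\,\mathrm{SD}$, $n-1$ denominator), treat/defer
concordance at vFFR ≤ 0.80, and the per-fidelity regression of accuracy
on reference vFFR with the classic ANCOVA slope-homogeneity F-test
(`y ~ group + x` against `y ~ group * x`).

The Wilcoxon signed-rank implementation is exact for small samples via
shift convolution over the (possibly tied, average) rank multiset --
identical to exhaustive enumeration of all $2^n$ sign vectors, which the
tests assert for $n \le 12$ -- with a continuity- and tie-corrected
normal approximation above. The point estimate is the Hodges--Lehmann
median of Walsh averages with its order-statistic CI. Two confidence
intervals are reported because their conventions differ: the
Walsh-average CI (achieved level 95.02% at $n = 40$) and the conservative
binomial order-statistic CI for the median, whose discrete achievable
level at $n = 40$ is 96.15% -- the odd level that paired benchmark tables
in this field print.

Pooling convention: when one case contributes several fidelity arms,
pooled summaries use all records; a per-case-median first reduction can
be obtained by filtering the records table, which is a plain data frame
with a documented CSV schema.

## Energy and cost model

Per the benchmark convention, each compute arm has a constant average
power draw -- e.g. 50 W as a conservative four-core CPU estimate, or a
GPU's 295 W maximum taken as its average -- so energy per case is
`power_w * duration_s / 3600` Wh. The printed worked examples
(8.44 Wh at 50 W x 607.5 s; 2.60 Wh at 295 W x 31.7 s; 3.32 Wh at
295 W x 40.5 s) reproduce to 2 d.p. Campaign cost is computed
dimensionally: Wh per case x cases / 1000 -> kWh, times the tariff, so
1000 cases at 8.44 Wh/case and 0.25/kWh cost 2.11 currency units for
8.44 kWh total. (Quoted figures of ~2110 for the same inputs arise from
a Wh/kWh slip of x1000 and are not reproduced.) Because power is
constant per arm, medians commute with the energy transform and
rank-based tests are invariant under it -- both are asserted in tests.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script runs use desk-scale configurations
chosen to exercise every code path on one CPU core:

* Poiseuille validation: ~20 000-cell full-fidelity tube at Re ≈ 30;
* unit fixtures: 300--3000-cell meshes of 40--75% lesions;
* cohort sweep: the default 40-vessel cohort at a reduced budget of
  $n_{\min} = 200$, $n_{\max} = 2000$, reference 4000 cells, paired flows
  1 and 3 mL/s.

All sweep results at this budget are scaled-down analogues: the
qualitative signatures (monotone median accuracy and duration in
fidelity, positive accuracy-vs-vFFR slope at low fidelity, concordance at
the 0.80 threshold) are the reproduction targets, never the absolute
clinical medians, which depend on patient anatomy and production solver
hardware.

## Known limitations

* Steady laminar rigid-wall Newtonian flow: no pulsatility, transition,
  wall compliance or non-Newtonian rheology.
* Severe lesions at hyperaemic flow are quasi-steady at best (see above);
  their vFFR carries cycle-mean uncertainty.
* Single focal lesion per vessel; no bifurcations.
* The structured swept mesh requires tube-like topology; strongly
  tortuous or branching anatomy is out of scope.
* $R_{mv}$ and $P_a$ are population conventions; absolute vFFR values are
  not personalized predictions.
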