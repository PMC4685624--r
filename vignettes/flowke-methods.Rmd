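---
title: "FlowKE: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FlowKE: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models, conventions and numerical choices behind
FlowKE, in the spirit of the methods sections that accompany other analysis
packages: what is computed, under which assumptions, which parameters
matter, and what the synthetic validation does and does not demonstrate.

## Data model and units

A 4D-flow acquisition is represented as a `VelocityField4D`: a regular
voxel lattice carrying three velocity components per voxel and cardiac
phase. On disk this is three scalar 4D NIfTI volumes (`vx/vy/vz`, cm/s, in
the physical frame of the affine) plus a JSON sidecar with the RR interval,
VENC, per-phase trigger times and blood density. No interchange standard
exists for 4D flow, so this layout is the package's own fixed convention.
Voxel indices are 0-based; physical positions come from the affine and are
in mm; velocities are stored in cm/s and converted to m/s for energies.
Conveniently, 1 mm/ms equals 1 m/s, so particle tracing works in mm and ms
without unit factors. Energies are reported in mJ, volumes in ml, indexed
KE in µJ/ml.

Segmentations (`MaskSeries`) are per-phase binary volumes with roles `lv`
(blood pool), `stationary` (static tissue) and `vortex`. A mask is
*defined* on a phase when it has at least one set voxel; undefined phases
propagate as `NA`, never as zero — an absent vortex delineation must not
masquerade as "zero KE inside the vortex".

## Preprocessing

**Velocity unwrapping.** Phase-contrast velocities alias modulo 2·VENC.
The package unwraps *temporally*: per voxel and component, whenever the
difference between consecutive phases exceeds VENC, an integer multiple of
2·VENC is added to minimise the temporal jump. The first phase is assumed
unaliased — at end-diastole speeds are typically far below VENC. A voxel
aliased identically at every phase produces no temporal jump and is not
recoverable; this is the documented limitation of any purely temporal
scheme, and such residual wraps are left to a user-supplied correction
mask. The order of operations is fixed as unwrap → background fit →
correction → resampling: fitting the smooth background on still-aliased
data would bias it, and unwrapping is insensitive to the small smooth
background offset.

**Background-phase correction.** Eddy-current-like offsets are modelled
per phase and component as a first-order spatial field
$v \approx a + b x + c y + d z$ fitted by least squares over
stationary-tissue voxels, then subtracted everywhere. Regressors are
physical coordinates centred on the stationary-voxel centroid for
conditioning; at least 16 non-coplanar voxels per phase are required, and
rank deficiency (e.g. a single-slice mask) is a hard error naming the
phase. Because the fit includes an intercept, the post-correction mean
stationary velocity is zero to solver precision, and re-fitting after
correction is a no-op (projection idempotence) — both are tested.

**Phase resampling.** The cycle is resampled by periodic linear
interpolation onto `nTarget` uniform timestamps over $[0, RR)$; 40 phases
is the conventional reconstruction target and the default. Linear
interpolation is chosen over splines because measured KE curves are
smooth at this temporal resolution and linearity preserves positivity and
locality; the error bound $\max|f''| h^2/8$ is exercised in the tests.

## Volumetrics and the cardiac phase partition

LV volume per phase is voxel count × voxel volume. ED is the phase of
maximum volume, ES of minimum (ties toward the earlier phase); SV = EDV −
ESV holds exactly by construction, EF = 100·SV/EDV. Rates use cyclic
central differences without smoothing (an optional 3-point moving average
exists for noisy manual masks, default off); PER/PFR are the extrema of
∓dV/dt over systole/diastole.

Within diastole, the E-wave runs from ES until dV/dt first falls below
α·PFR after the PFR peak, with α = 0.2 by default; the A-wave starts at
the onset of the last diastolic dV/dt local maximum (walking back while
dV/dt stays above α·PFR) and runs to ED; diastasis is the remainder, and
may be empty. The reference timing for E/A is transmitral flow; deriving
it from dV/dt is this package's surrogate — the two coincide for the
volume curves the phantom generates, but on real data with mitral
regurgitation or poor delineation they can differ, and the α threshold is
deliberately configurable.

## Kinetic energy

Per voxel, $KE = \tfrac12 \rho V_{voxel} \lVert v \rVert^2$ with ρ = 1050
kg/m³. Region curves are *spatial sums* per phase (mJ); "KE inside the
vortex" is read as the spatial sum over the vortex region followed by a
temporal average over the diastolic vortex phases — the per-voxel-mean
reading is rejected because published inside/outside curves share the mJ
scale of the total. Summation order is fixed (voxel index order), and on
vortex phases the total is assembled as inside + outside, so conservation
holds to the last ulp and is asserted exactly in the tests.

Summaries: systolic/diastolic temporal averages and peaks; averages
indexed to SV and EDV (×1000 → µJ/ml); curve variability as the
*sample* (n−1) SD over the full curve divided by its mean; the
inside-vortex fraction as a percentage of the diastolic vortex-phase KE.
ΔKE "from vortex formation to end-diastole" is implemented as the signed
change of maximal absolute value relative to the formation phase —
"change" is directional but its sign convention is not fixed elsewhere, so
the magnitude-maximal signed value is the least arbitrary choice; the same
rule serves diastasis-only ΔKE and Δvortex-volume.

## Particle tracing, FTLE and vortex delineation

Velocities are sampled by trilinear interpolation in space and linear
interpolation in time with periodic wrap; positions outside the grid are a
*signal* (the particle is frozen and flagged), not an error. Trajectories
use classic fourth-order Runge–Kutta; because trilinear interpolation
reproduces affine fields exactly, the rigid-rotation benchmark isolates
pure time-integration error and exhibits the expected ~16× error drop per
dt halving.

The FTLE field on a regular seed grid is
$\sigma = \ln\sqrt{\lambda_{max}(C)}/|T|$, with
$C = (\nabla\Phi)^\top\nabla\Phi$ and the flow-map gradient taken by
central differences over neighbouring seeds; λ_max uses the closed-form
trigonometric eigenvalue of a symmetric 3×3 matrix, vectorised over seeds.
The boundary seed layer and any seed whose stencil touched an escaped
trajectory are `NA`. Backward time (attracting structures) is the default
for bounding an inflow vortex; the span defaults to the elapsed diastole
up to the seeded phase, capped at RR/2.

The clinical reference procedure delineates LCS manually in short-axis
slices. The automated substitute here thresholds σ at the q-th percentile
within the LV (q = 0.90), applies a radius-1 morphological closing and
hole filling, intersects with the LV, and keeps the connected component
containing the basal-third LV centroid (the mitral inflow side; axis and
orientation configurable). Two structural properties of this rule are
worth knowing. First, the percentile threshold fixes the ridge "budget" at
roughly 10% of the LV volume, so volume recovery is only meaningful when
the true vortex occupies a comparable fraction of the LV — which is the
physiological situation (a ring of a few tens of ml in a 150–350 ml
ventricle); the synthetic validation therefore uses a vortex of ~12.5% of
its LV and recovers its volume within the stated ±25%. Second, backward
FTLE also ridges along the *wake* a translating ring leaves behind; the
basal-component selection suppresses most but not all of it, so extracted
masks lean toward the inflow side of the true ring. User-supplied vortex
masks bypass the heuristic entirely and are the recommended path when
manual delineations exist.

## KE time-curve patterns

Peak detection operates on the diastolic part of the total-KE curve after
a cyclic 3-point binomial smoother (¼, ½, ¼; default on): measured KE
curves are smooth, and without smoothing phase-wise noise spawns spurious
prominence candidates. Local maxima with prominence ≥ p·max(diastolic KE),
p = 0.10, are candidates; the earliest is E, the latest A. The curve is
*fused* (pattern 3) when fewer than two candidates survive or the
inter-peak trough exceeds θ·min(E, A) with θ = 0.7. Spill-over flags KE at
the onset of systole above s·max(diastolic KE), s = 0.5. Non-fused curves
with E < A are pattern 1, E > A pattern 2 (control-like instead for
control subjects); exact ties go to pattern 2 with a flag. The reference
classification was visual consensus; p, θ and s are this package's
operationalisation, are reported alongside every label, and the
recovery property (≥95% correct labels on 200 seeded replicates per
pattern at 10% noise) is part of the test suite at exactly these defaults.

Agreement with diastolic-dysfunction grades uses unweighted Cohen's kappa
with the Fleiss–Cohen–Everitt asymptotic standard error; the category
alignment is pattern 1 ↔ impaired relaxation, 2 ↔ pseudonormal,
3 ↔ restrictive, and undetermined grades are excluded (and counted).

## The synthetic generator

`makeLVCycle` emulates exactly the features the pipeline must recover,
with exact ground truth; realism beyond that is deliberately sacrificed.

- The LV is an axis-aligned ellipsoid (aspect 0.75 : 0.75 : 1.3) whose
  per-phase mask is cut to exactly `round(V/voxel volume)` voxels by
  ranking the ellipsoidal coordinate, so mask volumes match the prescribed
  curve to within half a voxel — exact volume control is what the
  volumetric tests need.
- The volume curve is built from logistic ejection/filling steps with an
  E/A split (default E/A volume ratio 2), producing a genuine two-peak
  filling pattern with nonempty diastasis; defaults EDV 150 ml, ESV 60 ml
  are textbook-normal values.
- Diastolic inflow carries a translating Hill-type vortex ring (radius 12
  mm); the A-wave is a basal inflow jet; systole is a smooth outflow. Jet
  and ring speeds per pattern are set so the synthetic KE curves show the
  E/A peak ratios characteristic of each pattern class (e.g. a dominant,
  separated E-peak for control-like curves).
- Stationary tissue is an ellipsoidal shell whose velocity is exactly the
  injected linear background field (also added to every voxel), so the
  background fit has a closed-form truth; Gaussian noise is added *before*
  wrap injection so unwrapping is exercised on corrupted data.
- Grid defaults are 48³ voxels at 3 mm and 40 phases over 1000 ms —
  acquisition-like resolution, small enough for seconds-scale generation.

What the phantom does *not* emulate: valve geometry, physiological
pressure–flow coupling, turbulence, wall motion artefacts, segmentation
error. Passing tests therefore demonstrate the correctness of the
computational chain against known truth, not clinical accuracy on patient
data.

`makeHillVortex` provides the classic spherical vortex (interior
rotational flow matched to an exterior dipole); its interior lab-frame
kinetic energy has the closed form $E = \tfrac{23}{21}\pi\rho U^2 a^3$
(the exterior adds the added-mass energy $\tfrac13\pi\rho U^2 a^3$,
recovering the classical total $\tfrac{10}{7}\pi\rho U^2 a^3$), used as
the convergence oracle for the discrete KE summation. Because a binary
voxel mask misclassifies boundary voxels, the discretisation error
fluctuates with the lattice phase; convergence is therefore assessed as
the geometric-mean error ratio per halving across two halvings (3 → 1.5 →
0.75 mm), which must be ≥ 3. `makeDoubleGyre` is the standard
time-periodic two-cell stream-function flow, extruded to a thin slab; only
its wall-normal velocity vanishes at the domain boundary (the
stream-function construction leaves tangential slip), and the FTLE
self-convergence check compares against a brute-force oracle at half the
seed spacing and a quarter of the step.

## Problem sizes and determinism

The test suite and the acceptance script run phantoms at 20³–48³ voxels,
9–40 phases, FTLE seed grids up to 73×33×3 (refined oracle), and 800
seeded classifier replicates; these sizes were chosen so the full
validation completes in minutes on one core while every check still
operates in its asymptotic regime. All generators are deterministic under
a fixed seed; pipeline runs with identical config and seed produce
byte-identical CSV/JSON outputs, and the full parameter set is snapshotted
in `provenance.json` next to every output.

## Known limitations

- Temporal unwrapping cannot recover voxels aliased at every phase.
- E/A timing from dV/dt is a surrogate for transmitral-flow timing.
- The FTLE ridge-percentile vortex delineation inherits a volume scale
  from the percentile budget and picks up wake structures behind fast
  rings; it is validated against synthetic truth only, and manual vortex
  masks take precedence when available.
- Pattern thresholds (p, θ, s) operationalise a visual grouping; on real
  cohorts they should be reported with the labels, as the pipeline does.
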