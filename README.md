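# FlowKE

Left-ventricular (LV) blood-flow **kinetic energy (KE) and vortex analysis
for 4D-flow cardiovascular MRI**, in R.

4D-flow CMR measures all three velocity components of moving blood over a
3D volume, time-resolved across the cardiac cycle. From such data plus LV
segmentations, FlowKE quantifies how much kinetic energy the LV blood pool
carries at every cardiac phase, how much of the diastolic energy resides
inside the inflow vortex ring, and which of the KE time-curve shapes seen
in heart failure a subject exhibits. The intended users are cardiovascular
imaging researchers analysing intracardiac flow energetics.

## What it computes

- **Voxel-wise KE**: for each voxel, KE = ½ m v², with m = ρ · V_voxel and
  ρ = 1050 kg/m³ for blood; the LV **KE time curve** is the sum over the
  LV blood pool per phase (mJ). Temporal averages and peaks are reported
  separately for systole and diastole, raw and indexed to SV or EDV
  (µJ/ml), together with the curve's coefficient of variation (SD/mean).
- **Preprocessing**: temporal unwrapping of velocity aliasing beyond VENC
  (wraps are modulo 2·VENC), background-phase correction by subtracting a
  linear fit v ≈ a + b·x + c·y + d·z over stationary tissue, and cyclic
  resampling of the cycle to a fixed number of phases (default 40).
- **Volumetrics**: LV volume curve from the segmentations; EDV, ESV,
  SV = EDV − ESV, EF, peak emptying/filling rates (PER/PFR) from cyclic
  central differences; partition of the cycle into systole, E-wave,
  diastasis and A-wave.
- **Vortex-ring delineation**: particle tracing (classic RK4) through the
  time-resolved velocity field, finite-time Lyapunov exponent fields
  σ = ln √λ_max(C) / |T| with C the Cauchy–Green tensor of the flow map,
  and extraction of the diastolic vortex ring from backward-FTLE ridges
  (Lagrangian coherent structures). KE is then split into
  inside-/outside-vortex parts with exact conservation.
- **Pattern classification**: diastolic KE peaks at the E- and A-waves are
  detected and each curve is labelled with one of the three heart-failure
  patterns — (1) E-peak KE lower than A-peak, (2) E-peak higher, (3) fused
  peaks — or control-like; agreement with diastolic-dysfunction grades is
  quantified with Cohen's kappa.
- **Synthetic ground truth**: a beating-LV phantom (exact volume curve,
  injected background field, wrap injection, translating Hill-type vortex
  ring) plus the analytic Hill-vortex and double-gyre benchmark flows.

Data formats: velocity volumes and masks are NIfTI (one 4D file per
velocity component) with a JSON sidecar (`rr_ms`, `venc_cm_s`,
`timestamps_ms`, `density_kg_m3`); curves are CSV; summaries are JSON.

## Worked example

Analyse a synthetic beating LV (32³ voxels at 4 mm, 30 phases, EDV 150 ml,
ESV 60 ml, control-like filling):

```r
library(FlowKE)

sim   <- makeLVCycle(dims = c(32, 32, 32), spacing = c(4, 4, 4), nPhases = 30)
model <- fitBackground(sim$field, sim$stationary)
field <- applyBackgroundCorrection(sim$field, model)

vc   <- computeVolumeCurve(sim$lv, voxelSpacing(field), phaseTimes(field),
                           rrInterval(field))
vols <- computeVolumetrics(vc)
ph   <- splitPhases(vc)
kef  <- computeKEField(field, density = 1050)
ke   <- partitionVortexKE(kef, sim$lv, sim$truth$vortex)
summarizeKE(ke, ph, vols, vortexVolume(sim$truth$vortex, voxelSpacing(field)))
```

which prints

```
VolumetricsSummary: EDV 150.0 ml, ESV 60.0 ml, SV 90.0 ml, EF 60.0%
  PER 477.1 ml/s, PFR 457.0 ml/s (ED phase 30, ES phase 13)
KESummary
  systolic avg 0.341 mJ (peak 1.61), diastolic avg 0.435 mJ (peak 2.36)
  per SV: 3.79 / 4.83 uJ/ml; per EDV: 2.27 / 2.9 uJ/ml; cv 1.6
  vortex: 78.7% of diastolic KE inside; dKE diastole 1.76 mJ, diastasis NA mJ
```

EDV/ESV recover the phantom's prescribed 150/60 ml to within one voxel;
78.7% of diastolic KE sits inside the vortex ring, in the range reported
for healthy filling; `classifyPattern(detectDiastolicPeaks(ke, ph),
"control")` labels the curve `control_like` (E-peak 1.87 mJ dominating the
A-peak 0.571 mJ, no fusion). Cohen's kappa on a published pattern-vs-grade
contingency table:

```r
cohenKappa(rbind(c(7, 3, 0), c(0, 2, 2), c(1, 4, 6)))
#> kappa 0.41 (SE 0.13, 95% CI 0.14-0.67)
```

`runPipeline(flowConfig(...))` chains all stages (simulate/read →
unwrap → background correction → volumetrics → KE → FTLE vortex →
classification) and writes `ke_curve.csv`, `ke_summary.json`,
`volumetrics.json`, `labels.csv`, `vortex.nii.gz`, a KE-curve plot and a
`provenance.json` snapshot of every parameter.

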