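Package: FlowKE
Title: Left-Ventricular Kinetic Energy and Vortex Analysis for 4D-Flow MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies left-ventricular (LV) blood-flow kinetic energy (KE)
    from time-resolved three-directional phase-contrast (4D flow) velocity
    fields. Provides readers and writers for velocity volumes and
    segmentations (NIfTI + JSON sidecar), phase-contrast preprocessing
    (temporal velocity unwrapping, linear background-phase correction from
    stationary tissue, cyclic phase resampling), LV volumetrics (EDV, ESV,
    SV, EF, peak filling and emptying rates, cardiac phase partition),
    voxel-wise KE fields and region-summed KE time curves, particle tracing
    and finite-time Lyapunov exponent (FTLE) fields for Lagrangian
    coherent-structure delineation of the diastolic vortex ring,
    classification of diastolic KE time-curve patterns seen in heart
    failure, Cohen's kappa agreement analysis, and a synthetic beating-LV
    flow generator with analytic ground truth (Hill's spherical vortex,
    double gyre) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, grDevices, graphics, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), e1071, withr, optparse
Config/testthat/edition: 3
biocViews: Software, ImageAnalysis, CardiovascularDisease
RoxygenNote: 7.3.3
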