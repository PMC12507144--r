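Package: aortaflow
Title: Aortic 4D Flow MRI Hemodynamics: Wall Shear Stress, Normative
    Atlases and Pulse Wave Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved three-directional
    phase-contrast ("4D flow") MRI of the thoracic aorta. Provides S4
    containers for velocity fields and lumen segmentations, phase-contrast
    MR angiogram construction and peak-systole detection, wall mesh and
    centerline extraction from binary segmentations, wall shear stress
    estimation from the near-wall velocity gradient, six-region anatomical
    partitioning, rigid mask-to-mask registration, healthy-cohort normative
    atlases with voxelwise abnormality heatmaps and incidence maps, pulse
    wave velocity from wavelet cross-spectrum delays of centerline flow
    waveforms, the accompanying cohort statistics (paired and unpaired t,
    exact tests, intraclass correlation), and a pulsatile tube-flow phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
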