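Package: striatlas
Title: Voxel-Wise 3D Interneuron Density Atlases of the Caudoputamen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise three-dimensional density atlases of genetically
    labeled interneuron populations (SST, PV, TH) in the mouse caudoputamen from
    per-cell coordinate tables registered to a common coordinate framework.
    Provides label-volume I/O (NRRD, NIfTI-1), construction of a 150-micron
    analysis grid with Chebyshev-distance boundary and ventricle exclusion,
    hemisphere-level bootstrap density estimation, mask-aware Gaussian smoothing,
    pooled quantile binning and subtype predominance maps, collapsed axis
    profiles with random-intercept linear mixed-effects gradient models
    (including sex interactions), subregion composition statistics with
    Sidak-corrected pairwise contrasts, and a synthetic reference-space and
    inhomogeneous-Poisson cell generator for self-contained validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
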