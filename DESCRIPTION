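Package: aqpquant
Title: Quantification Pipeline for Aquaporin Diffusion-MRI Reporter Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative analyses
    used to characterize aquaporin-1 (Aqp1) as a genetically encoded reporter
    for diffusion-weighted MRI and to assess its safety in mammalian cells.
    Covers apparent-diffusion-coefficient (ADC) estimation from multi-b-value
    magnitude image series with voxel-wise diffusion maps and the percent
    diffusivity-increase contrast statistic; dry-mass, volume, surface-area
    and sphericity morphometry from refractive-index tomograms via optical
    path length integration and iso-surface meshing; relative gene expression
    by the 2^(-ddCt) method with primer-efficiency QC and t-tests on delta-Ct
    values; and the per-assay formulas for T-cell stimulation percentage,
    phagocytic index, Matrigel invasion area, viability-normalized caspase
    activation, and ELISA quadratic standard-curve inversion. A synthetic-data
    module generates seeded ground-truth phantoms (Rician-noise diffusion
    series, ellipsoidal-cell tomograms, Ct tables, assay fixtures) so every
    estimator is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    tiff,
    png,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
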