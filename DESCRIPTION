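Package: lesionometry
Title: Tract-Specific Lesion Interaction Measures for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how white-matter lesions interact with specific
    tracts in diffusion MRI: voxel-based lesion load, whole-brain
    tractogram load, bundle volume, bundle load, whole-bundle Tractometry
    and lesion-restricted lesionometry sampling of microstructure maps.
    Derives the underlying per-voxel maps (iteratively weighted
    least-squares diffusion tensor fits with FA/MD/RD, rotationally
    invariant spherical-harmonic (RISH) features, apparent fibre density
    and fibre-orientation counts from fODF coefficients), reduces
    per-bundle microstructure to principal-component factors with
    sampling-adequacy checks, and runs a Bayes-factor correlation screen
    followed by ANCOVA covariate analysis with effect sizes and
    sample-size calculations. Includes a phantom generator (synthetic
    bundles, lesions, DWI, scalar maps and cohort tables) so the whole
    pipeline is testable end-to-end, plus TCK/TRK streamline and NIfTI
    volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    car,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
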