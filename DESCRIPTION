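Package: atlastrace
Title: Atlas-Space Quantification of Neural Tracing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying neural tracing
    experiments in a labeled reference-atlas space. Fits per-section planar
    affine transforms from control points, maps annotated neuron coordinates
    into atlas coordinates and classifies them into mediolateral cortical
    bins (cingulate/medial/lateral), reconstructs 3D injection volumes from
    outlined boundary points via convex-hull triangulation, Laplacian
    smoothing and voxelization with percent-overlap analysis against atlas
    structures, computes region-masked axon signal with per-animal
    normalization to innervation fractions, and assembles threshold-based
    connectivity maps. Ships a synthetic-data generator (toy atlas, sections,
    cells, injections, axon images) with serialized ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
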