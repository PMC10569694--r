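Package: lsmcount
Title: Automated Neuron Counting in Light-Sheet Volumes by Stereological
    Subvolume Sampling
Version: 0.1.0
Author: lsmcount developers
Maintainer: lsmcount developers <lsmcount@example.org>
Description: Design-based ("digital optical fractionator") neuron counting for
    3D light-sheet-style fluorescence volumes with anisotropic voxels. Places
    random cubic counting subvolumes strictly inside atlas-labeled brain
    regions, segments NeuN-like nuclei with a sparse-label random-forest voxel
    classifier over multi-scale image features, separates touching nuclei with
    an erosion-seeded anisotropic watershed, converts instance volumes to
    counts with a volume filter, and reports per-region densities, total-number
    estimates and cross-specimen variability. Includes a synthetic phantom
    generator with ground-truth instances so the whole pipeline is testable
    without microscope data, plus minimal multi-page TIFF and NIfTI-1 readers
    and writers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
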