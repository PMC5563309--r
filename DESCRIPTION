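Package: conetrack
Title: Deterministic and Cone-of-Uncertainty Probabilistic Streamline
    Tractography on Fiber ODF Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for real-time-style diffusion MRI
    tractography driven by per-voxel fiber orientation distribution
    function (fODF) peaks. Implements deterministic streamline
    propagation with a puncture-weighted direction update, and a
    probabilistic variant that samples each step inside a cone of
    uncertainty whose half-angle is extracted from the fODF as the
    angular distance at which the lobe falls to a chosen fraction of its
    peak value. Includes spherical-harmonic fODF evaluation and peak
    finding on tessellated spheres, NIfTI and TrackVis input/output,
    octree-indexed streamline selection, slab filtering, density maps
    with weighted Dice bundle comparison, and synthetic fiber phantoms
    (straight, curved, crossing) with analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    pracma,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
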