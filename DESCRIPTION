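Package: rhizodist
Title: Root Distance Histograms and Mixed Triangular-Gamma Models for
    Segmented 3D Root Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies root growth patterns from the soil perspective.
    Computes exact anisotropic Euclidean distance transforms of segmented
    3D root/soil volumes, extracts root distance histograms (RDHs) globally,
    per depth slab, and restricted to young roots via registered time-lapse
    root-age volumes, and fits a four-parameter mixed triangular-gamma
    distribution to them by binned maximum likelihood. Derives rhizosphere
    metrics: half-mean distance from root length density, mean root-soil
    distance, rhizosphere volume fractions at configurable extents, and a
    root surface density estimate. Includes synthetic generators for
    voxelized tap-root plus lateral root systems (static and time-lapse)
    with exact ground-truth root length, and for hexagonal and random 2D
    root point patterns with Monte Carlo distance statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tiff, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
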