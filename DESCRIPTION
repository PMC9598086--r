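Package: osteotrace
Title: Registration and Spatial Analysis of Bone Surface Modifications on 3D Bone Templates
Version: 0.1.0
Authors@R:
    person("osteotrace", "developers", email = "osteotrace@example.org", role = c("aut", "cre"))
Description: Tools for taphonomic and zooarchaeological analysis of bone surface
    modifications (tooth pits, tooth scores, cut marks, percussion marks)
    registered as 3D point data on long-bone template point clouds. Provides a
    canonical anatomical coordinate frame and an assemblage store with CSV/JSON
    persistence; polygonal and interval cropping with overlap-based survivorship
    heatmaps and MNE estimation; 3D second-order point-pattern statistics
    (Ripley K, empty-space F, nearest-neighbour G, pair correlation) with
    translation and border edge corrections and Monte Carlo complete-spatial-
    randomness envelopes; axial mark-intensity profiles and bivariate Morlet
    wavelet coherence with AR(1) surrogate significance; t-SNE embedding with
    DBSCAN cluster labelling; and circular statistics for tooth-score
    orientations (circular moments, Rayleigh and randomized
    Mardia-Watson-Wheeler tests, false positive risk). A synthetic-fixture
    module generates bone-like templates, mark patterns with known statistical
    structure, and crop sets with known overlap ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
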