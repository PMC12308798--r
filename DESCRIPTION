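Package: lamellr
Title: Lamellar Membrane Trajectory Analysis and Conformational Motif Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of planar lamellar lipid membranes from
    molecular-dynamics trajectories of two-tailed glycerolipids such as
    monomycoloyl glycerol (MMG). Covers membrane geometry (area per lipid from
    box dimensions and from periodic 2D Voronoi tessellation, electron-density
    profiles and peak-to-peak thickness), hydrocarbon-chain statistics
    (deuterium order parameters with ideal-geometry hydrogen reconstruction,
    tail tilt, splay and head-tail angles, rotational autocorrelation
    functions, in-plane radial distribution functions), an unsupervised
    conformational-motif stage built on per-lipid radial-angular three-particle
    correlation fingerprints compared with the structural similarity index and
    clustered via t-SNE and HDBSCAN with PCA validation, and lipid-water
    interface analysis (geometric hydrogen-bond detection, per-molecule bond
    statistics, intermittent hydrogen-bond autocorrelation, double-exponential
    fits of rotational decay). A synthetic-membrane generator produces planar
    single, stacked and interdigitated lamellar systems with controlled
    conformational motifs, chain order, headgroup dynamics and hydrogen-bond
    geometry so that every stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
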