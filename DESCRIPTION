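Package: trilodisp
Title: Landmark-Based Geometric Morphometrics and Disparity Analysis for
    Trilobite Cephala and Pygidia
Version: 0.1.0
Authors@R: person("TriloDisp", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for landmark/semilandmark geometric morphometrics of
    trilobite exoskeletal structures. Reads and writes 2D shape files in
    the tps and StereoMorph text dialects, validates configurations
    against built-in cephalon (16 landmarks, 4 curves) and pygidium
    (7 landmarks, 3 curves) templates, resamples semilandmark curves by
    arc length, performs generalised Procrustes superimposition from
    first principles, builds covariance-PCA morphospaces with virtual
    shape reconstruction, computes disparity metrics (sum of variances,
    sum of ranges, nearest-neighbour distance) through geological time
    with bootstrap intervals, and runs a measurement-error validation
    workflow (Kruskal-Wallis rank test, permutation test for homogeneity
    of multivariate dispersions, Tukey comparisons). Includes a seeded
    synthetic-data generator for end-to-end testing without external
    downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
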