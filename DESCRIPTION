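Package: ecgidipole
Title: Two-Step Single-Dipole Inverse Localization from Body Surface
    Potential Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive localization of ectopic ventricular activity
    (e.g. a premature ventricular contraction) as a single equivalent
    current dipole from multi-electrode body surface potential maps.
    Provides a boundary element method (BEM) forward solver for
    piecewise-homogeneous torso volume conductors built from closed
    triangulated surfaces, pseudoinverse dipole fitting with relative
    residual error (RRE) scanning over candidate source positions on a
    ventricular surface, greedy ranking of torso electrodes by
    significance criteria derived from singular values of the transfer
    matrix, and a two-step pipeline that re-solves the inverse problem
    with nested reduced electrode subsets.  Includes a synthetic phantom
    generator (nested ellipsoid torso, organs, strip electrode montage,
    noisy forward-computed maps with known dipole ground truth) used by
    the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
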