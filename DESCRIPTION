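Package: cybospec
Title: Unsupervised Solvatochromic Shift Prediction with the Perturbed Matrix Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised workflow for computing solvatochromic UV-vis
    spectra of a rigid solute in explicit solvent. Builds spherical
    non-periodic solvation boxes from a solvent unit cell, analyses
    solute-solvent structure (radial distribution functions, coordination
    numbers, continuous hydrogen-bond perception), clusters trajectory
    frames in an interaction feature space (PCA + partitioning around
    medoids with multi-criterion model selection), selects representative
    frames per cluster with a greedy randomized adaptive search procedure
    (GRASP), constructs charge-scaled collective frames, and computes
    perturbed excitation energies and Gaussian-broadened absorption
    spectra via the Perturbed Matrix Method, including cluster-weighted
    averaging and solvatochromic shift tables. Synthetic generators for
    trajectories with planted hydrogen-bond regimes, solvent cells, and
    physically consistent quantum-chemical reference sets make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
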