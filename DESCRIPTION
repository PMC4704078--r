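Package: SparseEMC
Title: EMC Reconstruction of 3D Bragg Intensities from Sparse Rotation Frames
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs the three-dimensional Bragg intensity of a crystal
    from very large numbers of non-oriented, sparse (a few hundred photons)
    diffraction frames recorded while the crystal rotates about a single known
    axis. Implements the expand-maximize-compress (EMC) expectation-maximization
    algorithm restricted to one-dimensional rotations, with Gaussian-peak
    seeding at predicted Bragg positions, two-stage resolution extension and
    photon-count rescaling; z-score peak segmentation, reciprocal-lattice
    refinement and ellipsoid integration of background-subtracted reflections;
    and validation metrics (reference assembly from true orientations,
    amplitude R factor, orientation-error histograms, reflection-condition
    checks, background-photon fraction). A synthetic-frame simulator with
    Poisson photon statistics makes every stage testable without experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Matrix, Rcpp, yaml, jsonlite, optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'SparseEMC-package.R'
    'io.R'
    'geometry.R'
    'emc.R'
    'validation.R'
    'peaks.R'
    'simulator.R'
    'config.R'
    'cli.R'
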