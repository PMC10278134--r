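Package: blufspec
Title: Vibronic Spectra and Structural Metrics for BLUF Photoreceptor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for quantum-chemistry and molecular-dynamics
    ensembles of flavin-binding BLUF photoreceptor domains. Computes vibronic
    absorption spectra from excited-state gradients via the vertical-gradient
    approximation and a second-order cumulant lineshape, broadens them with the
    inhomogeneous distribution of vertical excitation energies sampled along MD
    trajectories, aligns dark- and light-state spectra by a common shift and
    scale, summarises scalar observables (NMR chemical shifts, carbonyl stretch
    frequencies, excitation energies) with bootstrapped confidence intervals,
    and evaluates trajectory structural metrics: hydrogen-bond occupancy,
    interhelical angle, beta-sheet dihedral and backbone RMSD. Includes seeded
    synthetic-data generators with known analytic answers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'normal-modes.R'
    'vibronic.R'
    'ensemble-spectra.R'
    'ensemble-stats.R'
    'fixtures.R'
    'io.R'
    'methods-accessors.R'
    'structure-metrics.R'
    'pipeline.R'
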