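Package: relaxmx
Title: Slow Photocycle Relaxation Analysis for Time-Resolved Room-Temperature
    Crystallography
Version: 0.1.0
Authors@R: person("relaxmx", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the slow (seconds-to-minutes) relaxation of a
    light-induced cysteinyl-flavin photoadduct in LOV-domain crystals, combining
    in-crystallo UV-Vis absorption spectroscopy with refinement-based occupancy
    analysis of diffraction data. Provides a spectral pipeline
    (Savitzky-Golay smoothing, common-baseline subtraction, 390 nm trace
    extraction, monoexponential decay fitting), a miniature crystallographic
    engine (symmetry expansion, direct-summation structure factors, Fourier
    difference maps, R factors, scale and B-factor refinement), a two-state
    occupancy-scan procedure with a quantitative difference-map score,
    per-conformer exponential kinetics with cross-crystal normalisation,
    B-factor ordering metrics, detection of a tetragonal-to-orthorhombic
    crystal phase transition from symmetry-consistency time series, and
    seeded synthetic-data generators for every input so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
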