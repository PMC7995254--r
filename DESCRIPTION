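Package: exciton2des
Title: Frenkel Exciton Models and Global Lifetime Analysis of
    Two-Dimensional Electronic Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling strongly coupled chlorophyll assemblies such
    as the water-soluble chlorophyll protein (WSCP) and for analysing their
    ultrafast dynamics. Builds point-dipole excitonic couplings and Frenkel
    Hamiltonians from macromolecular structures, simulates two-dimensional
    electronic spectroscopy (2DES) datasets with exciton relaxation and
    coherence-dephasing kinetics, performs variable-projection global
    multiexponential fitting yielding two-dimensional decay-associated
    spectra (2D-DAS), and interprets the DAS in terms of exciton energies,
    relaxation gaps and effective transition-dipole magnitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
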