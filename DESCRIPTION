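Package: fullersense
Title: Post-DFT Analysis of Fullerene-Based Drug Sensors and Adsorbents
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating C60-based nanostructures as chemiresistive
    sensors or adsorbents for small-molecule analytes from quantum-chemistry
    result summaries. Computes conceptual-DFT reactivity descriptors (HOMO-LUMO
    gap, chemical hardness and softness, chemical potential, maximum
    charge-transfer capacity, electrophilicity-based charge transfer),
    adsorption and sensing metrics (cohesive energy, adsorption energy,
    Arrhenius recovery time, Richardson-type conductivity, dipole magnitude,
    mean polarizability), synthesizes Gaussian-broadened density-of-states and
    UV-Vis spectra with red-shift reporting, and performs real-space electron
    density topology on analytic promolecular model densities (reduced density
    gradient / NCI classification, ELF, LOL, bond-critical-point search with
    Abramov energy densities). Includes readers and writers for XYZ, Gaussian
    cube, and a JSON result-bundle schema, a reproducible synthetic
    sensor/analyte study-set generator, and report assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
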