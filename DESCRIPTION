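Package: ubamap
Title: Mapping Ubiquitin Recognition by Overlapping-UBA Solenoid Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising how a solenoid of overlapping
    ubiquitin-associated (UBA) domains recognises ubiquitin. Includes
    chemical shift perturbation (CSP) computation and interface mapping
    from HSQC titrations with fast-exchange Kd fitting, coordinate
    handling with Kabsch superposition, Calpha-geometry helix assignment
    and overlapping-UBA decomposition, template-superposition docking of
    monoubiquitins with steric-clash and K48/K63 isopeptide-linkage
    feasibility checks, paramagnetic relaxation enhancement (PRE)
    prediction from spin-label geometry, single-site isothermal titration
    calorimetry (ITC) simulation and fitting, and synthetic-data
    generators that emulate the corresponding experiments so the whole
    workflow is testable without external coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
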