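Package: cngk
Title: Analysis of pH-Gated Sperm Potassium Channel Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis chain for experiments on a pH-gated,
    K+-selective sperm channel (CNGK family): CASA-style trajectory
    kinematics with Savitzky-Golay average-swimming-path smoothing,
    signed path curvature and averaged-path velocity; voltage-clamp
    sweep reduction to IV relations, reversal potentials and
    K+-dependence slopes with Nernst/GHK closed forms and Woodhull-type
    Na+ block; Hill dose-response fitting, pH-titration fitting and the
    NH4Cl-to-intracellular-pH calibration; stopped-flow fluorescence
    normalization (dF/F, dR/R) and repeat averaging; and a
    multi-ligand chelator equilibrium solver (EGTA/ATP with
    Ca2+/Mg2+/H+) for free-ion concentrations in pipette solutions.
    A synthetic-data module generates every input type with known
    ground truth so the full pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
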