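Package: tcpcflow
Title: Hemodynamic Assessment of Total Cavopulmonary Connections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for time-resolved velocity and pressure
    fields on tetrahedral meshes of total cavopulmonary connections (TCPC,
    Fontan circulation). Computes wall-deformation metrics (cross-sectional
    area waveforms, deformation index), energy metrics (pressure drop,
    control-volume power loss), Lagrangian particle transport statistics
    (residence times, washout, hepatic flow distribution), and rigid-versus-
    compliant comparisons. Includes a synthetic four-branch junction generator
    with analytic rigid and prescribed-wall-motion flow fields for validation,
    and a lumped compliant-chamber surrogate of the connection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
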