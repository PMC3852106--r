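Package: kvdelay
Title: Delay-Current Electrophysiology and Kv1.1 Expression Analysis in
    Dentate Granule Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking the dendrotoxin-sensitive delay
    current (I_D) of hippocampal dentate granule cells to action-potential
    response delays and to Kv1.1 transcript abundance. Provides sweep-level
    containers and recording quality control for patch-clamp data,
    current-clamp feature extraction (resting potential, input resistance,
    membrane time constant, rheobase, spike delay, jitter, input/output
    curves), voltage-clamp characterization of subtraction-isolated currents
    (Boltzmann activation/inactivation, inactivation kinetics, reversal
    potential, Nernst reference), a multi-level RT-qPCR quantification
    pipeline (efficiency, delta-delta-CT fold changes, abundance ranking,
    z-score co-expression, phenotype-expression correlation), ROI
    densitometry with line profiles, a normality-gated two-group statistical
    decision tree, and a single-compartment conductance-based granule-cell
    simulator used to generate fully synthetic study cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
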