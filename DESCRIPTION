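Package: badnet
Title: Dynamic Network Model of Stress-Mediated BAD Phosphorylation and
    Apoptosis in Prostate Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 13-protein signaling network that controls BAD
    phosphorylation at Ser112/Ser136 in prostate cancer cells under growth
    factor (EGF) and psychological-stress (epinephrine/VIP) stimuli together
    with eight targeted inhibitors. Provides fixed-step Runge-Kutta
    integration of the Hill-kinetics ODE system with steady-state-closed
    dephosphorylation rates, two nested apoptosis readout models (BAD-only
    and BAD plus Mcl-1/CREB), genetic-algorithm parameter estimation against
    normalized phospho-protein and apoptosis tables, local time-averaged
    sensitivity analysis, and drug-combination synergy quantification (Loewe
    isobologram index and a total-dose combination index) including the
    stress-triggered synergism-pattern switch. A synthetic-data generator
    emulates the underlying experimental designs so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
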