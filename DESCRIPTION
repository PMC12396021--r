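Package: beclinduality
Title: Dual-Role Beclin-1 Dynamics of Autophagy and Apoptosis in Ischemic Stroke
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation model of the crosstalk between
    Beclin-1-induced autophagy and Caspase-3-mediated apoptosis in neurons
    under ischemic stress. Implements the five-state model (Beclin-1, cleaved
    Beclin-1, autophagosomes, damaged mitochondria, active Caspase-3) with
    saturable autophagic flux and a bistable Caspase-3 switch; analytic and
    numerical machinery for the isolated Caspase subsystem (bistability
    conditions, critical points, saddle-node bifurcation scans); Latin
    hypercube parameter ensembles with mechanism-knockout scenarios;
    Beclin-1 viability-window scans; in-silico knockdown and overexpression
    populations; and golden-hour stress-duration threshold analysis with
    candidate neuroprotective interventions. Includes chi-square scenario
    comparisons with Bonferroni correction and Wald confidence intervals
    for apoptotic proportions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
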