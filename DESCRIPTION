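Package: loewescreen
Title: Fixed-Ratio Loewe-Additivity Synergy Screening for Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Panel", "Screening Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing drug-combination viability screens run with a
    fixed-ratio (ray) design. Fits four-parameter logistic dose-response
    curves to viability data normalised to vehicle control, inverts them to
    effect-level doses (IC50 to IC80), computes the Loewe-Additivity
    combination index across the 50-80 percent growth-inhibition range,
    classifies single-agent sensitivity and combination synergy, and rolls the
    results up to panel-level summaries. A synthetic panel generator with a
    controllable true (constant) Loewe interaction index provides ground truth
    for every pipeline stage, and a small set of scalar assay metrics (wound
    closure, relative-to-control ratios, ellipsoidal tumour volume and fold
    change, percent-positive-cell scoring) covers the common downstream
    readouts of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
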