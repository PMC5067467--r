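Package: devalsim
Title: System-Level Neural Simulation of Instrumental Devaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate neural model of goal-directed behavior and the
    instrumental devaluation effect in rats. Implements leaky, striatal and
    onset rate units, dopamine-gated Hebbian plasticity with activity traces,
    three basal ganglia-thalamo-cortical selection loops, a basolateral
    amygdala/insular-cortex valuation subsystem and striato-nigro-striatal
    dopaminergic spirals, together with a simulated operant-chamber
    environment, the full pre/post-training lesion experiment battery, and
    the associated statistical analysis (binned learning curves, repeated
    measures and mixed ANOVA, paired t-tests, devaluation-effect verdicts).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
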