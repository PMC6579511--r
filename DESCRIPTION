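Package: flytaste
Title: Quantification of Fly Taste-Neuron Calcium Imaging and Proboscis
    Extension Behavior
Version: 0.1.0
Authors@R:
    person("Flytaste", "Maintainers", email = "maintainers@flytaste.example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantifying gustatory sensory responses
    in flies: sub-pixel rigid registration of two-photon GCaMP movie stacks
    by upsampled cross-correlation, ROI delta-F/F0 trace extraction, peak and
    integrated response statistics, responder classification against the
    water response, proboscis extension response (PER) scoring and group
    summaries, directional-PER tallies, and from-scratch repeated-measures
    ANOVA (one-way within-subject and two-way mixed) with Bonferroni and
    Dunnett post-tests. A synthetic-data module generates imaging sessions
    and behavioral datasets with known ground truth so every stage is
    verifiable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
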