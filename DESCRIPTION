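Package: galpop
Title: Population and Behavioral Analysis of Pregnancy-Induced Remodeling in a Hypothalamic Parenting Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the quantitative analyses used to
    characterize pregnancy-induced remodeling of galanin-expressing medial
    preoptic area (MPOA-Gal) neurons: intracellular trace feature extraction
    (baseline firing, resting potential, silent-cell classification,
    depolarization block, action-potential half-width, spontaneous
    postsynaptic currents), event-aligned calcium population analysis
    (Z-scoring, activated-neuron detection, onset latency, onset-ordered
    hierarchical clustering), tuning and selectivity scoring, linear
    discriminant stimulus separability with Rand-Index quantification, and
    behavioral-sequence statistics (bout summaries, transition-probability
    matrices with rank-sum edge tests, Kaplan-Meier latency analysis). A
    synthetic-data generator with recorded ground truth emulates the
    recording structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    survival,
    tibble,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
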