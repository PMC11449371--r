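Package: ganex
Title: Generative Adversarial Simulation of Expression Trajectories and
    Time-Resolved Co-Expression Module Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a Wasserstein generative adversarial network with
    gradient penalty (WGAN-GP) on two-condition bulk expression profiles,
    interpolates in latent space between condition-matched "resembled
    fakes" to simulate the unobserved intermediate time course, detects
    weighted co-expression modules on the simulated trajectories,
    correlates module eigengenes with a per-sample behavioral trait
    measured in real samples, aligns modules on the simulated time axis,
    and rescues intermediate-stage differentially expressed genes missed
    by endpoint-only comparisons.  Includes a synthetic-data generator
    with planted modules and trajectory archetypes for validation, and a
    hypergeometric gene-set enrichment step for module annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust
Config/testthat/edition: 3
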