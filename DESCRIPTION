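Package: defvar
Title: Partitioning the Effects of Plant Defense Variability on Herbivores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counterfactual simulation tools for decomposing the effect of
    variability in plant chemical defenses on herbivore performance into the
    contributions of nonlinear averaging (Jensen's effect), selective feeding,
    their interaction, and a residual attributable to unmodelled mechanisms
    such as constraints on physiological tracking. Includes Hill and penalized
    smooth dose-response curves with posterior-style uncertainty draws,
    herbivore leaf-choice preference estimation with a cluster bootstrap,
    two-point dietary dose distributions, a crossed Monte-Carlo decomposition
    with equal-tailed credible intervals, and a synthetic-experiment generator
    with analytic ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
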