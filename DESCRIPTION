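Package: anglesel
Title: Angling-Induced Selection on Fish Behavior, Morphology, and Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates fishery-induced phenotypic selection from replicated
    pond angling experiments on juvenile carp. PIT-antenna detection logs are
    summarized into boldness metrics (feeding-spot visit rates, shelter use)
    with rank-order consistency and Lessells-Boag repeatability; landmark
    photographs are processed by generalized Procrustes superimposition,
    Burnaby orthogonal projection to remove dorsoventral arching, and
    principal component analysis; capture-based survival is modelled with an
    AICc-ranked set of nested logistic regressions, and coefficients are
    linearized (Janzen-Stern) into SD- and mean-standardized selection
    gradients.  An individual-based simulator of the pond experiment
    (correlated traits, Poisson foraging visits, per-session capture hazard,
    landmark generation) makes the whole pipeline runnable and testable
    without access to the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    lme4,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
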