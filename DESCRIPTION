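Package: codibm
Title: Individual-Based Eco-Evolutionary Simulation of Northeast Arctic Cod
    Under Fishing and Climate Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, mechanistic simulator of a Northeast Arctic
    cod (Gadus morhua) population with explicit annual energy and oxygen
    budgets, two heritable life-history traits (appetite and the intercept of
    the probabilistic maturation reaction norm), six instantaneous mortality
    components including size-selective trawl and gillnet fisheries,
    Beverton-Holt recruitment with gonad-weighted midparent inheritance, and
    parametric climate-warming scenarios. Provides spin-up initialisation,
    replicated multi-century scenario experiments, and summary surfaces
    (trait means, growth curves, maturation schedules, population size,
    mortality decomposition, emergent heritability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
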