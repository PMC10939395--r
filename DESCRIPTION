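Package: cmtracer
Title: Inference of Actively Grazing Constitutive Mixotrophs from
    Labeled-Prey Amplicon Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying actively grazing constitutive
    mixotrophs (CMs) from paired labeled-prey (+BrdU / -BrdU) 18S amplicon
    incubation experiments, matching the resulting bacterivorous ASVs to
    light-microscopy taxa at genus level to estimate potential versus
    active CM abundance and proportion, and relating those estimates to
    environmental covariates with quasipoisson and quasibinomial
    generalized linear models with a counting-effort offset and variance
    inflation factor collinearity pruning. Includes a synthetic-data
    generator with serialized ground truth so every stage of the pipeline
    can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
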