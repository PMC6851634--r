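Package: streamlitter
Title: Litter Breakdown and Its Biotic Mediators Across Streambed Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing standardized litter-breakdown bioassays
    (cotton strips and the Tea Bag Index) deployed in the benthic and
    hyporheic zones of streams, together with the biological structure of
    the streambed community that mediates breakdown. Computes degree-day
    normalized exponential decay coefficients, Tea Bag Index stabilization
    (S) and decay (K) parameters, carbon biomass from organism counts and
    body dimensions, rarefied Shannon alpha-diversity via Hill numbers,
    EcoPlate metabolic activity and diversity, Bray-Curtis NMDS ordination
    with permutation-tested vector fitting, random-factors ANOVA and causal
    three-step mediation analysis over nested linear mixed models. Includes
    a forward simulator of the full hierarchical survey design with known
    ground truth, and an end-to-end pipeline driver.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
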