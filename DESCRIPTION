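Package: agmacap
Title: Agmatine Production Capacity of Gut Microbial Community Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of gut microbial communities
    to predict their capacity to produce agmatine, the decarboxylation product
    of arginine implicated in drug-microbiome-host interactions. Provides a
    stoichiometric model data structure with flux balance analysis under a
    small total-flux penalty, homology-driven refinement of strain models with
    agmatine transport and extracellular arginine decarboxylase reactions,
    conversion of food-frequency records into participant-specific dietary
    exchange bounds, assembly of abundance-weighted community models with
    flux-biomass coupling constraints, per-participant production-capacity
    prediction with species attribution, side-product yields and in-silico
    nutrient supplementation screens, and the statistics of a four-way
    host-microbe-drug-nutrient plate screen (growth area under the curve,
    robust fluorescence quantiles, interaction linear models and
    hypergeometric enrichment). A synthetic-data module generates every input
    the pipeline consumes so that all stages are testable without external
    resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    boot,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
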