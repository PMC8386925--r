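Package: aadiet
Title: Amino Acid Compound-Specific Isotope Dietary Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of individual human diets from compound-specific
    stable isotope values of bone-collagen amino acids. Provides GC-C-IRMS
    data reduction (norleucine normalisation, nitrogen calibration curves,
    derivatization-carbon correction with full error propagation), prediction
    of amino-acid isotope values for archaeological cereals from modern-grain
    offsets with charring correction, concentration-dependent Bayesian mixing
    models with metabolic routing of carbon and nitrogen (bulk protein-routed
    and whole-diet models, a source-amino-acid protein model, and a whole-diet
    model with trophic amino acids and an optional olive-oil source) sampled
    by Metropolis-Hastings, and between-sex cohort statistics. A synthetic
    data module generates every input the pipeline consumes so that all
    stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
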