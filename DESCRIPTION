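Package: micronet
Title: Compositional Co-Occurrence Networks, Keystone Taxa and Percolation
    Robustness for Gut Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Microbiome", "Networks Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers sparse signed co-occurrence networks from compositional
    species abundance tables via centered log-ratio transformation and
    Meinshausen-Buhlmann neighborhood selection with StARS stability-based
    penalty selection. Provides global and node-level network topology
    metrics, k-core decomposition, keystone-taxon detection, a percolation
    framework for random and targeted node-removal attacks with the NR50 and
    percolation-threshold statistics, subsampled-network ensemble stability
    analysis, metabolic-health/obesity phenotype classification from clinical
    biomarkers, and a synthetic compositional data generator with known
    conditional-dependence structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
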