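Package: layernet
Title: Cross-Study Expression Integration and Layered Signaling Network
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates independent microarray expression cohorts into one
    case-control compendium (quantile normalization, empirical-Bayes
    location/scale batch adjustment), screens differential genes with a
    permutation-calibrated SAM statistic over resampled virtual cohorts,
    detects dense modules in a cancer signaling interaction network with
    the MCODE algorithm, maps recurrent differential drivers onto modules,
    stratifies module nodes into four subcellular layers with
    neighbor-vote imputation, and tests (module x layer) gene sets for
    hypergeometric over-representation with Benjamini-Hochberg control.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    sva,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
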