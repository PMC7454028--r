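Package: demeflow
Title: Temporal Migration and Genetic Structure in Biennial Plant Demes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time demographic-genetic simulation of the two temporally
    offset demes of a biennial, semelparous plant connected by temporal
    migrants (individuals that delay reproduction by one year), together with
    the statistics used to quantify temporal genetic structure: AMOVA-based
    F-statistics with permutation tests, hierarchical F-statistics with locus
    bootstraps, Nei diversity summaries, discriminant analysis of principal
    components (DAPC) and centroid distances, tagged-rosette temporal
    migration and mortality estimators, genotype file readers and writers
    (GenAlEx-like CSV, STRUCTURE text, Arlequin .arp), a Balding-Nichols
    synthetic microsatellite generator, and a scenario-grid driver over
    temporal migration rates and migration event probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, MASS, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
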