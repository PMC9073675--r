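Package: mrtline
Title: Mutation Rate and Selection Inference for the C. elegans Mortal
    Germline Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing heat-sensitive mortal-germline (Mrt) assay
    data in Caenorhabditis elegans: threshold classification of lines from
    replicate time-to-sterility records with right-censoring, exact Poisson
    (Garwood) confidence intervals for the genome-wide Mrt mutation rate
    from mutation-accumulation experiments, mutational-target-size
    arithmetic, mutation-selection-balance inference of selection
    coefficients under near-complete selfing, stochastic simulators for
    neutral transmission in single-descent lines and finite selfing
    populations, a synthetic assay-data generator, and a nearest
    phenotyped-neighbour permutation analysis on haplotype trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
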