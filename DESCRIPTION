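Package: dupOrigins
Title: Classification, Epoch Dating and Divergence Analysis of Gene Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene duplicates by mode of origin (whole-genome,
    tandem, proximal, dispersed) from gene order and homolog pair lists,
    detects colinear (synteny) blocks by dynamic-programming anchor chaining,
    dates dispersed duplicates by colinearity conservation against an ordered
    outgroup ladder, and calls transposed and relocated polyploidy-born
    ("relocated gamma") duplicates. Includes a forward-in-time genome
    evolution simulator (genome triplication, fractionation, gene relocation
    bursts, single-gene duplications, clock-scaled Ks/Ka) with ground-truth
    origin labels, plus Ks-distribution secondary-peak detection,
    expression and promoter-motif regulation divergence measures, and GO
    fold-enrichment profiling with Fisher exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap
Config/testthat/edition: 3
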