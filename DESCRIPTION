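Package: haplomap
Title: Haploid-Progeny Genetic Linkage Mapping and Macrosynteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of genetic linkage maps from haploid progeny of
    dikaryotic fungal hybrids, and assessment of chromosome-scale synteny
    against a congeneric reference genome. Provides homokaryon selection from
    multilocus microsatellite profiles, per-marker segregation diagnostics,
    staged two-point and multipoint maximum-likelihood mapping with EM
    estimation of recombination fractions, Kosambi map distances, genome-length
    and map-coverage estimation, Oxford-grid synteny assignment, collinearity
    scoring, synteny-break classification, and windowed homolog-density
    statistics. A meiosis and genome-rearrangement simulator supplies ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
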