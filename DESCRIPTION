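Package: ntbaZones
Title: Nonspecific TF Binding Affinity Profiles and Genomic Zone Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes nonspecific transcription-factor binding affinity (nTBA)
    along DNA by sliding-window ensemble averaging of a motif collection under
    a Fermi-Dirac (or Maxwell-Boltzmann) binding-probability model, normalizes
    epigenomic coverage tracks, scores intra-chromosomal Hi-C contact matrices,
    tests marker enrichment in detected interactions with a rank-sum statistic,
    and classifies fixed-size genomic bins into Inactive, Poised and Active
    Genomic Zones by a weighted combination of k-means and Gaussian-mixture
    probabilities. Includes seeded synthetic-data generators for every input
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    data.table,
    jsonlite,
    mclust,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
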