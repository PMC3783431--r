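Package: msarray
Title: Multi-Species Endocrine Microarray Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing and analysing multi-species oligonucleotide
    microarrays used to monitor endocrine disruption in unsequenced fish.
    Includes conserved-window 60-mer probe selection across multiple
    alignments, a synthetic single-color array data generator with known
    ground truth, pooled-reference construction and multiple-loess
    normalization, replicate-median probe summarization and cross-species
    gene consolidation, sum-squared ranking of modulated transcripts,
    spatial hybridization artifact detection, Spearman phenotype
    correlation screening, fold-change power planning, and 2^dCT qPCR
    relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
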