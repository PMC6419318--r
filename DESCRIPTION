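Package: genefamkit
Title: Integrative Gene Family Identification from Orthogroups and Profile-HMM Searches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for defining plant gene families (kinase families such as
    the MAP3Ks) by integrating orthogroup clustering with ranked profile-HMM
    homology searches. Implements subfamily-specific E-value threshold
    determination from reference members, a cluster-aware decision table with
    completion ratios, diagnostic-motif verification by position weight matrix
    scanning with exact p-values, collinearity chaining and five-way gene
    duplication typing, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction, and stress-response expression labeling from FPKM tables.
    Includes a synthetic-fixture simulator with planted ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
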