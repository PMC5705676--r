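Package: ProteoTrim
Title: Species-Disjoint Reference Proteomes and Quantitative Metaproteomics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-species label-free metaproteomics. Performs
    deterministic in-silico tryptic digestion of reference proteomes,
    detects peptides shared between community member species by exact
    string matching, and excises them from the protein sequences to
    produce species-disjoint ("trimmed") reference proteomes suitable
    for spectral database searching, together with overlap matrices and
    per-protein trim reports. Downstream, provides quantifiable-protein
    filtering on per-group valid-value fractions, two-group differential
    abundance testing with an S0-moderated Welch statistic and
    permutation-based FDR, and direction-aware pathway
    over-representation analysis by one-sided Fisher's exact test with
    Benjamini-Hochberg correction. Seeded simulators generate proteomes
    with planted cross-species shared peptides, intensity matrices with
    planted group effects and missingness, and pathway annotations with
    planted enrichment, each with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
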