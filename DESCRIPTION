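Package: woxkit
Title: Codon Usage, Physicochemistry, Phylogeny and Expression Analysis for
    Plant Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream characterization of plant gene families across
    related species: relative synonymous codon usage (RSCU/RFSC) with
    high-frequency-codon calling and heterologous expression-host ranking
    by codon-frequency ratios; ExPASy-style protein physicochemical
    profiles (molecular weight, theoretical pI, instability index,
    aliphatic index, GRAVY); neighbor-joining phylogeny with bootstrap
    supports and anchor-based clade assignment; gene-structure statistics
    and promoter cis-acting element scanning with IUPAC consensus motifs;
    and 2^-ddCt relative qPCR expression with dual reference genes.
    Includes seeded synthetic-data generators with machine-readable truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
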