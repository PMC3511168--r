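Package: snotrace
Title: Deep Ancestry and Intragenomic Mobility of Small Nucleolar RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for tracing small nucleolar RNA
    (snoRNA) families to the Last Eukaryotic Common Ancestor (LECA) and for
    testing the evolutionary stability of their intronic locations. Implements
    Dollo-parsimony ancestral-state reconstruction of binary presence/absence
    characters on a rooted species tree, antisense (seed-and-extend, ungapped)
    mapping of C/D-box snoRNA guide sequences onto SSU/LSU ribosomal RNA with
    cross-species alignment-column binning of modification-site loci,
    projection of intron positions onto host-protein alignments with snoRNA
    occupancy and cross-supergroup homology verdicts, Shannon-entropy
    expression-breadth comparison of host versus non-host genes, a
    total-evidence intersection of the independent lines of evidence, and a
    fully seeded synthetic-data generator that plants ancestral families,
    mobility events, guide target sites and expression profiles with complete
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
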