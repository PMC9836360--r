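Package: mitocub
Title: Codon Usage Bias Analysis for Mitochondrial and Nuclear Genomes
Version: 0.1.0
Authors@R:
    person("Mito", "CUB Developers", email = "mitocub@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative codon usage bias analysis of organellar
    and nuclear coding sequences: relative synonymous codon usage (RSCU)
    profiling, Wright's effective number of codons (ENc) with the ENc-GC3
    neutrality plot, correspondence analysis of codon usage matrices,
    hierarchical clustering of genome-level RSCU profiles, tRNA adaptation
    index (tAI/stAI) computation from tRNA gene copy numbers, the
    permutation-based S-test for translational selection, and a wobble
    pairing decodability analysis of tRNAomes.  Includes readers for CDS
    FASTA and GenBank flat files, support for alternative genetic codes
    (notably the mold mitochondrial code), and a synthetic-data generator
    producing gene sets under tunable mutational bias and translational
    selection for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
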