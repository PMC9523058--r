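Package: ambercode
Title: Detection and Proteomic Validation of Amber Stop-Codon Reassignment in Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and proteomically validate alternative genetic
    code usage (translation table 15, in which the amber stop codon TAG is
    read as glutamine) in bacteriophage genomes. Provides six-frame ORF
    prediction under alternative translation tables, coding-density-based
    genetic code assignment with contig-size-dependent thresholds, GC-skew
    replichore analysis, construction of layered dual-code proteome search
    databases with upstream start-extension variants and reversed decoys,
    in-silico tryptic digestion with monoisotopic mass computation,
    target-decoy false discovery rate filtering of peptide identifications,
    codon-level mapping of peptides onto the genome, classification of
    stop-codon and start-codon readthrough evidence, corroboration with
    de novo sequencing tags, and a synthetic-data generator for end-to-end
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
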