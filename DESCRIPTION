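Package: tipscape
Title: Transposable-Element Insertion Polymorphism Maps from Pangenome Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates pangenome structural variants as transposable-element
    insertion polymorphisms (TIPs) with the 80-80 family rule and an
    overlap-resolution cascade, relates TIPs to gene models (events, TIP
    genes, insertion-density profiles, subspecies conservation), partitions a
    genome into polymorphic-TE, consensus-TE and non-TE space for histone-mark
    and methylation quantification, calls cold-responsive genes and TEs from
    expression matrices, builds consensus TE-gene co-expression networks with
    cis/trans classification and a TE-derived lncRNA filter, and performs
    TIP-based association scans and haplotype survival comparisons. A seeded
    synthetic-pangenome generator with complete truth tables supports
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    limma,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
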