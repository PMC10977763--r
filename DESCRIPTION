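Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing annotated animal mitochondrial
    genomes: parsing and validating circular gene annotations (gene
    tables or GenBank flat files), intergenic spacer and overlap
    accounting, base composition with AT- and GC-skew statistics,
    codon usage and RSCU under the invertebrate mitochondrial genetic
    code, signed circular gene-order comparison with breakpoint
    counts and rearrangement event classification (shuffling,
    translocation, inversion), constrained cloverleaf folding of tRNA
    genes with arm-presence calls, and concatenated 13-gene
    supermatrix preparation for phylogenetics. A seed-controlled
    synthetic mitogenome generator makes every stage testable without
    external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
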