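# Shared fixtures built from the packaged data files.

table2_annotation <- function() {
  parse_gene_table(mito_example("desmaulus_table2.tsv"),
                   genome_length = 16608)
}

ancestral_order <- function() {
  read_gene_order(mito_example("ancestral_gastropod_order.tsv"))
}

table3 <- function() {
  utils::read.delim(mito_example("desmaulus_table3.tsv"),
                    check.names = FALSE)
}

table4_counts <- function() {
  t4 <- utils::read.delim(mito_example("desmaulus_table4_codons.tsv"))
  stats::setNames(t4$count, t4$codon)
}

# Small circular signed orders for rearrangement unit tests.
toy_order <- function(n = 10) {
  gene_order(LETTERS[seq_len(n)], rep(1L, n))
}
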