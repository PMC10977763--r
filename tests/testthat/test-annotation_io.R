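test_that("gene table parsing recovers the full 37-gene annotation", {
  ann <- table2_annotation()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(nrow(ann$genes), 37L)
  expect_equal(sum(ann$genes$category == "PCG"), 13L)
  expect_equal(sum(ann$genes$category == "tRNA"), 22L)
  expect_equal(sum(ann$genes$category == "rRNA"), 2L)
  # names normalized from the raw table labels
  expect_true(all(c("trnD", "rrnS", "rrnL", "NAD4L", "CYTB") %in%
                    ann$genes$name))
  cox1 <- ann$genes[ann$genes$name == "COX1", ]
  expect_equal(cox1$length, 1551L)
  expect_equal(cox1$start, 1L)
})

test_that("malformed and degenerate tables are rejected with clear errors", {
  expect_error(parse_gene_table("", 1000), "empty|header")
  expect_error(parse_gene_table("gene\tstrand\tstart\tend\tlength\nX\tH\tfoo\t10\t10",
                                1000), "row")
  expect_error(parse_gene_table("gene\tstrand\tstart\tend\tlength\nX\tH\t5\t2000\t10",
                                1000), "genome_length")
  expect_error(parse_gene_table("wrong\theader\nX\tH", 1000), "header")
})

test_that("printed lengths in disagreement with coordinates are corrected", {
  txt <- paste("gene\tstrand\tstart\tend\tlength\tstart_codon\tstop_codon\tanticodon",
               "COX1\tH\t1\t300\t299\tATG\tTAA\t",
               "trnA\tH\t320\t390\t71\t\t\tTGC", sep = "\n")
  expect_warning(ann <- parse_gene_table(txt, 500), "authoritative")
  expect_equal(ann$genes$length[ann$genes$name == "COX1"], 300L)
})

test_that("gene name normalization maps field synonyms and flags unknowns", {
  expect_equal(as.character(normalize_gene_name(
    c("NAD4l", "COI", "COX1", "ND5", "Cytb", "12S rRNA", "tRNA-Leu2"))),
    c("NAD4L", "COX1", "COX1", "NAD5", "CYTB", "rrnS", "trnL2"))
  out <- normalize_gene_name(c("COX1", "mystery_orf"))
  expect_equal(attr(out, "unknown"), c(FALSE, TRUE))
  expect_equal(as.character(out)[2], "mystery_orf")
})

test_that("spacer/overlap accounting closes the circle", {
  ann <- table2_annotation()
  rep <- spacers_and_overlaps(ann)
  # one record per gene (circular closure)
  expect_equal(nrow(rep$pairs), nrow(ann$genes))
  # gene lengths + spacers - overlaps tile the circle exactly
  expect_equal(sum(ann$genes$length) + rep$total_spacer - rep$total_overlap,
               ann$genome_length)
  # the four overlapping pairs with their printed sizes
  ov <- rep$overlaps
  expect_equal(nrow(ov), 4L)
  expect_equal(ov$gap[ov$upstream == "trnW"], -2L)
  expect_equal(ov$gap[ov$upstream == "trnG"], -1L)
  expect_equal(ov$gap[ov$upstream == "rrnS"], -1L)
  expect_equal(ov$gap[ov$upstream == "trnV"], -10L)
  # control-region analog: the largest spacer sits between trnF and trnT
  mx <- rep$spacers[which.max(rep$spacers$gap), ]
  expect_equal(mx$gap, 648L)
  expect_equal(mx$upstream, "trnF")
  expect_equal(mx$downstream, "trnT")
})

test_that("abutting genes get gap zero and row order does not matter", {
  txt <- paste("gene\tstrand\tstart\tend\tlength\tstart_codon\tstop_codon\tanticodon",
               "COX1\tH\t1\t100\t100\tATG\tTAA\t",
               "trnA\tH\t101\t150\t50\t\t\tTGC",
               "trnC\tH\t161\t200\t40\t\t\tGCA", sep = "\n")
  ann <- parse_gene_table(txt, 220)
  rep <- spacers_and_overlaps(ann)
  expect_equal(rep$pairs$gap[rep$pairs$upstream == "COX1"], 0L)
  expect_equal(rep$pairs$gap[rep$pairs$upstream == "trnA"], 10L)
  # wrap pair: trnC -> COX1 across the origin
  expect_equal(rep$pairs$gap[rep$pairs$upstream == "trnC"], 20L)
  # permuting input rows changes nothing (sorted by start internally)
  lines <- strsplit(txt, "\n")[[1]]
  ann2 <- parse_gene_table(paste(lines[c(1, 4, 2, 3)], collapse = "\n"), 220)
  expect_identical(spacers_and_overlaps(ann2)$pairs, rep$pairs)
})

test_that("census reports extremes, per-category totals, and strands", {
  cen <- census(table2_annotation())
  expect_equal(cen$longest_gene, "NAD5")
  expect_equal(cen$longest_length, 1872L)
  expect_equal(cen$shortest_gene, "trnA")
  expect_equal(cen$shortest_length, 51L)
  expect_equal(cen$length_by_category$tRNA, 1485L)
  expect_equal(cen$length_by_category$PCG, 11394L)
  # categories sum to the total gene count
  expect_equal(Reduce(`+`, cen$by_category), cen$n_genes)
  expect_setequal(cen$l_strand_genes,
                  c("trnM", "trnY", "trnC", "trnW", "trnQ", "trnG",
                    "trnE", "trnT"))
})

test_that("gene table emission round-trips through the parser", {
  ann <- table2_annotation()
  txt <- write_gene_table(ann)
  ann2 <- parse_gene_table(txt, ann$genome_length)
  expect_identical(ann$genes, ann2$genes)
})

test_that("GenBank emission round-trips, including wrap and complement", {
  gen <- generate_mitogenome(genome_spec(seed = 3))
  gb <- tempfile(fileext = ".gb")
  write_genbank(gen$annotation, gb)
  back <- parse_genbank(gb)
  expect_identical(gen$annotation$genes, back$genes)
  expect_identical(gen$annotation$sequence, back$sequence)
  expect_identical(gen$annotation$genome_length, back$genome_length)
})

test_that("GenBank conventions: complement strand, wrap join, empty file", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST   400 bp    DNA     circular   UNA",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "     CDS             complement(100..300)",
    "                     /gene=\"COX1\"",
    "     tRNA            join(390..400,1..40)",
    "                     /gene=\"trnA\"",
    "                     /anticodon=\"TGC\""), gb)
  ann <- parse_genbank(gb)
  cox1 <- ann$genes[ann$genes$name == "COX1", ]
  expect_equal(cox1$strand, "L")
  expect_equal(c(cox1$start, cox1$end), c(100L, 300L))
  wrap <- ann$genes[ann$genes$name == "trnA", ]
  expect_equal(c(wrap$start, wrap$end, wrap$length), c(390L, 40L, 51L))

  writeLines(c("LOCUS       EMPTY   100 bp    DNA     circular   UNA",
               "FEATURES             Location/Qualifiers"), gb)
  expect_warning(ann0 <- parse_genbank(gb), "no gene features")
  expect_equal(nrow(ann0$genes), 0L)
})
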