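test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_mitogenome(genome_spec(seed = 7))
  g2 <- generate_mitogenome(genome_spec(seed = 7))
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$truth$codon_counts, g2$truth$codon_counts)
  g3 <- generate_mitogenome(genome_spec(seed = 8))
  expect_false(identical(g1$annotation$sequence, g3$annotation$sequence))
})

test_that("generated genomes carry the full complement and a sane layout", {
  gen <- generate_mitogenome(genome_spec(seed = 17))
  ann <- gen$annotation
  expect_equal(ann$genome_length, 16608L)
  expect_equal(nchar(ann$sequence), 16608L)
  cen <- census(ann)
  expect_equal(cen$n_genes, 37L)
  expect_equal(cen$by_category$PCG, 13L)
  expect_equal(cen$by_category$tRNA, 22L)
  expect_equal(cen$by_category$rRNA, 2L)
})

test_that("every generated PCG is a clean ORF with the configured codons", {
  gen <- generate_mitogenome(genome_spec(seed = 19))
  cen <- start_stop_census(gen$annotation)
  expect_equal(nrow(cen), 13L)
  expect_true(all(cen$start_codon == "ATG"))
  expect_true(all(cen$stop_codon == "TAA"))
  # no internal terminators under code 5
  stops <- c("TAA", "TAG")
  for (g in cen$gene) {
    cds <- extract_cds(gen$annotation, g)
    n <- nchar(cds)
    internal <- substring(cds, seq(1, n - 3, 3), seq(3, n - 3, 3))
    expect_false(any(internal %in% stops))
  }
})

test_that("infeasible specs fail before generation", {
  expect_error(generate_mitogenome(genome_spec(genome_length = 14000L)),
               "infeasible")
  expect_error(genome_spec(at_content = 1.2))
})

test_that("rearrangement application is exact, logged, and involutive", {
  ref <- canonicalize_gene_order(ancestral_order())
  # empty event list: identical order
  out0 <- apply_rearrangements(ref, list())
  expect_identical(out0$order, ref)
  # a named inversion flips signs in place, and re-applying restores
  ev <- list(list(type = "inversion",
                  genes = c("NAD4", "NAD4L"), after = NA))
  once <- apply_rearrangements(ref, ev)$order
  expect_false(orders_equivalent(once, ref))
  twice <- apply_rearrangements(once, ev)$order
  expect_identical(twice$labels, ref$labels)
  expect_identical(twice$sign, ref$sign)
  # overlapping random events are refused
  expect_error(
    apply_rearrangements(ref, list(
      list(type = "inversion", genes = c("NAD4", "NAD4L"), after = NA),
      list(type = "inversion", genes = c("NAD4L", "trnT"), after = NA))),
    "overlap")
})

test_that("seeded random events replay identically and log their truth", {
  ref <- canonicalize_gene_order(ancestral_order())
  a <- apply_rearrangements(ref, 3, seed = 99)
  b <- apply_rearrangements(ref, 3, seed = 99)
  expect_identical(a$order, b$order)
  expect_identical(a$log, b$log)
  expect_length(a$log, 3L)
  expect_true(all(vapply(a$log, `[[`, character(1), "type") %in%
                    c("shuffling", "translocation", "inversion",
                      "inverted_translocation")))
})

test_that("the emitted bundle round-trips through the annotation readers", {
  gen <- generate_mitogenome(genome_spec(seed = 29))
  dir <- tempfile()
  paths <- write_synthetic_bundle(gen, dir)
  expect_true(all(file.exists(paths)))
  back <- parse_genbank(paths[["genbank"]])
  expect_identical(gen$annotation$genes, back$genes)
  expect_identical(gen$annotation$sequence, back$sequence)
  fa <- read_fasta(paths[["fasta"]])
  expect_equal(unname(nchar(fa[1])), gen$annotation$genome_length)
})
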