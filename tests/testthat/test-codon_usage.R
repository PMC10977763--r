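test_that("invertebrate mitochondrial code has the forced family structure", {
  code <- genetic_code(5)
  fams <- code$families
  expect_equal(sum(lengths(fams)), 64L)
  expect_equal(length(fams$S), 8L)                  # UCN + AGN
  expect_setequal(fams$W, c("UGA", "UGG"))          # UGA reads Trp
  expect_setequal(fams[["*"]], c("UAA", "UAG"))     # 2-member stop family
  expect_true("AUA" %in% fams$M)
})

test_that("CDS extraction honors strand and origin wrap", {
  seqn <- paste(rep("ACGT", 50), collapse = "")   # 200 nt
  txt <- paste("gene\tstrand\tstart\tend\tlength\tstart_codon\tstop_codon\tanticodon",
               "COX1\tH\t191\t11\t21\tATG\tTAA\t",     # wraps the origin
               "NAD1\tL\t101\t130\t30\tATG\tTAA\t", sep = "\n")
  ann <- parse_gene_table(txt, 200, sequence = seqn)
  wrap <- extract_cds(ann, "COX1")
  expect_equal(nchar(wrap), 21L)
  expect_equal(wrap, paste0(substr(seqn, 191, 200), substr(seqn, 1, 11)))
  # a frame remainder is warned about and trimmed
  txt2 <- sub("191\t11\t21", "191\t10\t20", txt)
  ann2 <- parse_gene_table(txt2, 200, sequence = seqn)
  expect_warning(tr <- extract_cds(ann2, "COX1"), "divisible by 3")
  expect_equal(nchar(tr), 18L)
  lstr <- extract_cds(ann, "NAD1")
  expect_equal(lstr, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seqn, 101, 130)))))
  expect_error(extract_cds(ann, "trnA"), "no gene")
})

test_that("start/stop census matches the published codon columns", {
  cen <- start_stop_census(table2_annotation())
  expect_equal(nrow(cen), 13L)
  expect_equal(cen$start_codon[cen$gene == "COX1"], "ATT")
  expect_equal(cen$stop_codon[cen$gene == "COX1"], "TAA")
  tag <- cen$gene[cen$stop_codon == "TAG"]
  expect_setequal(tag, c("NAD4L", "NAD5", "NAD3"))
  # all starts/stops canonical under code 5
  expect_true(all(cen$canonical_stop))
})

test_that("codon counting reads frames and matches a brute-force tally", {
  expect_equal(count_codons("ATGTAA"), c(AUG = 1L, UAA = 1L))
  expect_equal(count_codons("ATGTTATAA"),
               c(AUG = 1L, UAA = 1L, UUA = 1L))
  expect_error(count_codons("ATGT"), "divisible")
  set.seed(9)
  cds <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  got <- count_codons(cds)
  # independent position-by-position tally
  oracle <- table(vapply(seq(1, 298, by = 3), function(i)
    chartr("T", "U", substr(cds, i, i + 2)), character(1)))
  expect_equal(got[sort(names(got))],
               setNames(as.integer(oracle), names(oracle))[sort(names(got))])
  # permutation invariance of the pooled count
  two <- c(substr(cds, 1, 150), substr(cds, 151, 300))
  expect_equal(count_codons(rev(two)), got)
})

test_that("RSCU reproduces the published per-family values", {
  ala <- rscu(c(GCU = 84, GCC = 19, GCA = 41, GCG = 15))
  expect_equal(round(ala$rscu[ala$codon == "GCU"], 2), 2.11)
  leu <- rscu(c(UUA = 336, UUG = 160, CUU = 126, CUC = 26, CUA = 67,
                CUG = 43))
  expect_equal(round(leu$rscu[leu$codon == "UUA"], 2), 2.66)
  ser <- rscu(c(AGA = 85, AGG = 83, UCU = 113, UCC = 44, UCA = 83,
                UCG = 31, AGU = 100, AGC = 43))
  expect_equal(round(ser$rscu[ser$codon == "AGA"], 2), 1.17)
  stop2 <- rscu(c(UAA = 174, UAG = 105))
  expect_equal(round(stop2$rscu[stop2$codon == "UAA"], 2), 1.25)
  expect_equal(round(stop2$rscu[stop2$codon == "UAG"], 2), 0.75)
})

test_that("RSCU families sum to family size, scale-invariantly", {
  counts <- table4_counts()
  code <- genetic_code(5)
  cu <- rscu(counts, code)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(cu$count[cu$codon %in% fam])
    if (tot > 0)
      expect_equal(sum(cu$rscu[cu$codon %in% fam]), length(fam))
  }
  # uniform counts give RSCU 1 everywhere in the family
  uni <- rscu(setNames(rep(7, 4), c("GCU", "GCC", "GCA", "GCG")))
  expect_equal(uni$rscu[uni$aa == "A"], rep(1, 4))
  # scaling all counts leaves RSCU unchanged
  cu2 <- rscu(counts * 3, code)
  expect_equal(cu$rscu, cu2$rscu)
  expect_error(rscu(c(GCU = -1)), "negative")
})

test_that("codons per thousand normalize and match a hand tally", {
  expect_equal(unname(codons_per_thousand(c(AUG = 1, UAA = 1))),
               c(500, 500))
  counts <- table4_counts()
  cpt <- codons_per_thousand(counts)
  expect_equal(sum(cpt), 1000)
  total <- sum(counts)
  for (cd in c("UUA", "GCU", "UGA"))
    expect_equal(cpt[[cd]], 1000 * counts[[cd]] / total)
  expect_error(codons_per_thousand(numeric()), "empty")
})

test_that("pooled PCG codon usage equals the generator's ground truth", {
  gen <- generate_mitogenome(genome_spec(seed = 13))
  cu <- codon_usage(gen$annotation)
  got <- setNames(cu$count, cu$codon)
  truth <- gen$truth$codon_counts
  expect_equal(got[names(truth)], as.numeric(truth), ignore_attr = TRUE)
  expect_equal(sum(cu$count), sum(truth))
})
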