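# mitochar

Characterization of circular animal mitochondrial genomes in R: the
standard descriptive battery a mitogenome announcement paper reports,
as a tested, reusable pipeline.

Metazoan mitogenomes are compact circular molecules (~15–17 kb) carrying
a near-universal complement of 37 genes: 13 protein-coding genes (PCGs),
22 tRNAs, and 2 rRNAs. Their characterization follows a well-worn
recipe — gene-content census and coordinate accounting, base-composition
asymmetry, codon-usage bias, gene-order comparison against an ancestral
arrangement, tRNA secondary-structure calls, and preparation of a
concatenated PCG supermatrix for phylogenetics. `mitochar` implements
each stage behind a small, composable API, and ships a seed-controlled
synthetic mitogenome generator so every stage is exercisable without any
sequence download.

## What it computes

- **Annotation accounting** (`parse_gene_table`, `parse_genbank`,
  `census`, `spacers_and_overlaps`): circular 1-based coordinates,
  gene-name normalization onto the canonical 37-label vocabulary
  (COI/COX1, ND5/NAD5, …), intergenic spacers and overlaps including the
  origin-wrapping pair, and per-category totals.
- **Composition and skew** (`composition_profile`,
  `region_composition`): AT-skew = (A − T)/(A + T) and
  GC-skew = (G − C)/(G + C), scale-invariant, for the whole genome, any
  gene, or pooled sense-strand categories.
- **Codon usage** (`count_codons`, `rscu`, `codons_per_thousand`) under
  the invertebrate mitochondrial genetic code (NCBI table 5: 8-codon Ser
  family, UGA = Trp, AUA = Met, stops UAA/UAG). For codon *i* in
  synonymous family *F*: RSCU_i = n_i · |F| / Σ_{j∈F} n_j.
- **Gene-order rearrangement analysis** (`breakpoints`,
  `synteny_blocks`, `classify_events`): signed circular permutations,
  canonicalized at COX1+, compared against a packaged ancestral
  gastropod arrangement; events typed with the field's vocabulary —
  shuffling (past tRNAs only), translocation (past PCGs/rRNAs),
  inversion (strand switch), and inverted translocation.
- **tRNA cloverleaf folding** (`fold_cloverleaf`, `mismatch_report`,
  `validate_anticodon`): exhaustive constrained-layout search over
  acceptor/D/anticodon/T arms with Watson–Crick/wobble/mismatch scoring,
  and arm-absence calls for the degenerate D-armless serine and
  T-armless alanine tRNAs common in invertebrate mitogenomes.
- **Supermatrix preparation** (`build_supermatrix`,
  `write_inference_configs`): 13-PCG concatenation with exact partition
  bookkeeping; FASTA/PHYLIP/NEXUS export and ready-to-run partition and
  MrBayes configuration blocks (GTR+F+R6; nst=6, rates=invgamma).
- **Synthetic data** (`genome_spec`, `generate_mitogenome`,
  `generate_trna`, `apply_rearrangements`): AT-rich circular genomes
  with clean ORFs, template tRNAs with known layouts, and seeded typed
  rearrangements with ground-truth logs.

## Worked example

The package ships a transcription of a published gastropod mitogenome
gene table (`desmaulus_table2.tsv`, a 16,608 nt circle) and the
ancestral gastropod gene order:

```r
library(mitochar)

ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"),
                        genome_length = 16608)
census(ann)
#> mito_census: 37 genes (13 PCG / 22 tRNA / 2 rRNA)
#>   longest NAD5 (1872 nt), shortest trnA (51 nt)
#>   L-strand genes: trnM, trnY, trnC, trnW, trnQ, trnG, trnE, trnT

spacers_and_overlaps(ann)
#> spacer_report: 28 spacers (total 1483 nt, max 648), 5 abutments, 4 overlaps (total 14 nt)
```

The largest spacer (648 nt, between trnF and trnT) is the control
region; the four overlaps (2, 1, 1 and 10 nt) include the 10 nt
trnV–rrnL overlap. Skews from the genome's base percentages:

```r
at_skew(27.73, 42.47)   # -0.2099715  -> T-rich genome
gc_skew(18.08, 11.71)   #  0.2138301  -> G over C
```

Codon-usage bias from published codon counts, under code 5:

```r
cu <- rscu(c(GCU = 84, GCC = 19, GCA = 41, GCG = 15))
round(cu$rscu[cu$codon == "GCU"], 2)
#> [1] 2.11
```

Rearrangements relative to the ancestral gastropod:

```r
ref <- read_gene_order(mito_example("ancestral_gastropod_order.tsv"))
classify_events(order_from_annotation(ann), ref)
#> rearrangement_report: 5 breakpoints, 5 synteny blocks, 3 events (greedy, not necessarily minimal)
#>   - translocation of [trnM trnY trnC trnW trnQ trnG trnE] across [trnF NAD5 trnH NAD4 NAD4L trnT trnS2 CYTB NAD6 trnP NAD1 trnL2 trnL1 rrnL trnV rrnS]
#>   - inverted_translocation of [trnS2 CYTB NAD6 trnP NAD1 trnL2 trnL1 rrnL trnV rrnS] across [trnF NAD5 trnH NAD4 NAD4L trnT]
#>   - inversion of [trnF NAD5 trnH NAD4 NAD4L] in place
```

The trnM–trnE cluster relocates intact downstream of ATP6, and the
large span from trnF to rrnS is explained by inversion plus
translocation — the classic pattern for this lineage.

A fully synthetic genome, with every stage runnable end to end:

```r
gen <- generate_mitogenome(genome_spec(seed = 7))
out <- write_synthetic_bundle(gen, tempdir(), "demo")
run_characterize(run_config(genbank = out[["genbank"]],
                            ref_order = mito_example("ancestral_gastropod_order.tsv"),
                            out = "demo_report", seed = 7))
```

## Scope

Upstream steps are out of scope by design: read assembly, de novo
annotation (use MITOS or similar), alignment, and tree inference itself.
The supermatrix module emits the partition and command files that
IQ-TREE and MrBayes consume; running them is the user's step. See
`vignettes/mitochar-methods.Rmd` for the models, parameter choices, and
known limitations.
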