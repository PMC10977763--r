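---
title: "Methods and design notes for mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

This vignette records the models, conventions, parameter choices, and
known limitations behind each stage of the pipeline — the decisions a
maintainer or reviewer would want spelled out.

## Coordinates and annotation conventions

Mitogenomes are circular; all coordinates are 1-based inclusive on the
deposited (H, heavy) strand, matching the way published organization
tables print them. A gene whose `end` is smaller than its `start` wraps
the origin, with length `(L - start + 1) + end`. Internally no half-open
representation leaks out of the accessors.

Printed gene tables are treated as partially untrusted input: the
`length` column is cross-checked against the coordinates, and on
disagreement the coordinates win, with a warning. This matters in
practice — published organization tables commonly carry stale length or
intergenic columns (the packaged example table's intergenic column is
internally inconsistent with its own coordinates in several rows, e.g.
the control region prints 12 where the coordinates give 648). The same
posture applies to genome length: published reports sometimes print two
or three conflicting totals for one molecule (the packaged example's
source prints 16,605, 16,608, and 16,572 in different places), so the
genome length is an explicit argument everywhere and the fixtures carry
16,608, the value consistent with the composition table. Strand labels
in the source text and its table also disagree about which tRNAs sit on
the L strand; the table's Direction column is followed, being the only
reading consistent with the gene-order figure.

Nested or same-start genes sort by `(start, -length)` with ties flagged.
Spacer/overlap accounting pairs each gene with its successor by start
position plus the circular wrap pair, so there are always exactly as
many adjacency records as genes, and
`sum(gene lengths) + spacers - overlaps == genome length` holds
identically — a closure invariant the tests assert on both the real
table and generated genomes.

## Composition and skew

AT-skew `(A - T)/(A + T)` and GC-skew `(G - C)/(G + C)` are
scale-invariant, so counts and percentages give identical values; a zero
denominator yields `NA` with a warning rather than an error. Per-gene
and per-category profiles pool *sense-strand* nucleotides (L-strand
genes reverse-complemented first); the whole-genome profile uses the
forward strand, which is the convention under which published
whole-genome skews reproduce. IUPAC ambiguity codes are excluded from
all four counts and reported separately. Report writers round
percentages to 2 d.p. and skews to 3 d.p.; internal values stay at full
precision.

## Codon usage and the genetic code

The default code is NCBI translation table 5 (invertebrate
mitochondrial), obtained from Biostrings and wrapped with the structure
RSCU needs: synonymous families partition the 64 codons by amino acid,
and the two terminators form their own 2-member family (published RSCU
tables print RSCU for UAA/UAG, which requires exactly this treatment).
Table 5 is forced by the family arithmetic of such tables — an 8-codon
serine family (UCN + AGN), UGA as tryptophan, AUA as methionine.

`rscu()` computes `RSCU_i = n_i |F| / sum(n_j, j in F)` from whatever
codon-count table it is given; it deliberately does not assume counts
come from the 13 PCGs, because published codon-count tables are
sometimes tallied over a different frame than their caption implies (the
packaged example's counts sum to ~5,500 codons, the size of the whole
genome rather than of the PCG set). The RSCU arithmetic is
frame-independent, so the published values reproduce exactly either way.
Families with zero total get RSCU 0 and are flagged rather than
producing 0/0.

## Gene-order comparison

A gene order is a signed circular permutation; `+` is the H strand. Two
orders are equivalent under rotation and under full reversal with sign
flip (reading the circle from the other strand). Canonicalization
anchors COX1 first with `+` orientation, the convention of comparative
gene-order figures. Breakpoints count query adjacencies absent from the
reference, with each adjacency closed under the reading-direction
symmetry `(a, b) ~ (-b, -a)`; the count is symmetric and zero exactly on
equivalent orders. Synteny blocks are maximal runs contiguous and
co-oriented in both orders, with a reversed-and-flipped run counting as
one inverted block; they partition the genes.

Event classification builds a greedy scenario transforming the
reference into the query and types each move with the field's
three-category vocabulary: *shuffling* moves a block past tRNAs only,
*translocation* past at least one PCG or rRNA (crossing distance
measured on the working reference), *inversion* switches strand in
place, and *inverted translocation* both moves and flips. The greedy
works left to right on the canonical forms: at the first disagreeing
position it considers two candidate moves — pull the query's next run
into place, or push the reference's displaced run out to its query
position — and picks the candidate that explains a strand flip if
exactly one does, otherwise the smaller moved block (accepting the
pushed-run candidate only when it strictly increases agreement, which
guarantees termination). The two-candidate choice resolves the inherent
direction ambiguity of a translocation (moving block X right past span
M is indistinguishable from moving M left past X) in favor of the more
parsimonious moved set; on 100 seeded simulations of up to three
non-overlapping typed events the recovered event-type multiset matches
the generator's log in 100% of trials. The scenario is explicitly *not*
guaranteed minimal — exact minimal multi-type rearrangement scenarios
are computationally hard — and the report carries a `heuristic` flag
saying so.

The packaged ancestral gastropod arrangement is config data, not code:
comparative figures print it only graphically, so the fixture encodes
the standard ancestral gastropod order from the comparative literature,
and is clearly labeled as a curated reference fixture.

## tRNA cloverleaf folding

No published folding algorithm accompanies mitogenome announcements
(structures typically come from the MITOS server), so the constrained
search here is this package's own definition, with all parameters in
`cloverleaf_params()`. The layout, 5′→3′: acceptor stem 7 bp; link
0–3 nt; D arm (stem 3–4 bp, loop 4–12 nt); link 0–2 nt; anticodon arm
(stem 4–5 bp, loop exactly 7 nt, anticodon at the loop's central
3 positions); variable region 3–23 nt; T arm (stem 4–5 bp, loop
3–9 nt); acceptor 3′ side; ≤2 discriminator nt. Degenerate variants
replace the D arm with an unstructured 4–15 nt span and/or drop the T
arm entirely, emulating the D-armless serine and T-armless alanine
tRNAs of many invertebrate mitogenomes.

Scoring: +2 per Watson–Crick pair, +1 per G·U wobble, −2 per mismatch.
All admissible layouts are enumerated (per-stem statistics are
precomputed per placement, so the enumeration is a table join; a 72-nt
tRNA folds in well under a second); the best layout wins by score, then
total paired count, then fewest mismatches, then shortest variable
loop, with a layout placing an expected anticodon centrally preferred
ahead of score. An arm is *present* iff its stem in the best layout has
at least 3 paired (WC or wobble) positions and positive score — so
"lacks the DHU arm" means no acceptable D stem exists under the
constraints, not merely a weak one, and an absent arm reports no pairs.
Sequences admitting no layout at all return a fold-failure result with
all arms absent rather than an error. T/U are equivalent on input;
output uses the input alphabet.

Anticodon validation decodes the reverse complement of the anticodon
and allows standard third-position wobble (anticodon 5′ base U pairs
codon-third A or G; G pairs C or U).

## The synthetic generator

The generator's defaults are the study conditions of the packaged
example: a 16,608 nt circle at 70% A+T carrying the 37-gene complement
in the packaged gene order, gene lengths equal to the example table's,
D-armless trnS1/trnS2 and T-armless trnA, one 648-nt control-region
analog after trnF, and small random spacers (0–20 nt) elsewhere.
Bases are drawn per-position with the AT target; PCGs are built
codon-by-codon from the non-terminator pool (weighted by the same base
distribution, i.e. rejection of stops), so every PCG is a clean ORF
with its configured start/stop codons. The realized genome A+T lands
about one percentage point below the target because excluding the
AT-rich terminators slightly depletes A/T in coding sequence; the tests
assert ±2 points. All randomness flows through one seeded stream per
call, saved and restored around it, so a fixed (spec, seed) is
bit-reproducible and never perturbs the caller's RNG.

Template tRNAs build stems by reverse-complement construction (which
preserves the AT fraction) and place the anticodon centrally. For
arm-omitted templates the unstructured replacement span is redrawn
until it contains no acceptable stem — including the base a shortened
anticodon stem could cede to the D region — so the generator's
arm-absence labels are genuinely ground truth rather than
probably-true; without this, a few percent of D-less draws contain
chance stems that any honest folder must report.

Typed rearrangement simulation draws non-overlapping blocks (1–3
genes) that never touch the canonical anchor: shufflings move tRNA-only
blocks past 1–2 tRNAs, translocations cross a span of 4–8 genes
containing a PCG or rRNA (the span exceeding the block keeps the moved
set unambiguous), inversions flip in place, and inverted translocations
move and flip. The exact realized log is returned for recovery tests.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: substitution-model evolution along a
phylogeny, genes spanning the origin (supported by the readers, not
emitted by default), annotated gene overlaps with shared sequence
(overlap analytics are exercised on the real table fixture instead),
truncated stop codons completed by polyadenylation, heteroplasmy, and
sequencing or assembly error. Real tRNAs also deviate more from the
template geometry than the generator's fixed loop and link sizes.

## Problem sizes and determinism

The test suite and acceptance script use the sizes the analyses were
designed at: the 37-gene table fixture for all accounting checks, 100
seeded rearrangement simulations with up to 3 events for event-type
recovery, 50 seeded template tRNAs (cycling full / D-less / T-less
configurations) for arm-configuration recovery, and full 16.6-kb
synthetic genomes for end-to-end determinism; the whole suite runs in
well under a minute on one CPU. Determinism is asserted at three
levels: identical fold layouts for identical sequences, bit-identical
genomes for a fixed seed, and byte-identical report bundles for a fixed
configuration.

## Supermatrix and inference artifacts

Alignment is an input; the module concatenates per-gene alignments in
the canonical order COX1, COX2, COX3, ATP6, ATP8, NAD1–6, NAD4L, CYTB,
gap-fills taxa missing a gene (`-` by default, configurable) without
ever touching a present character, and emits FASTA, relaxed PHYLIP, and
NEXUS with a sets block, all byte-stable. Inference configuration
follows the common published setup: per-gene partitions under GTR+F+R6
with 1000 ultrafast bootstrap replicates recorded for the ML side, and
a MrBayes block with `nst=6 rates=invgamma`, 2,000,000 generations,
sampling every 1000, 25% burn-in, two runs. Whether published analyses
partitioned per gene or ran one concatenated block is often
unstated; per-gene partitions are emitted by default with a
`merge_partitions` switch for the single-block reading. Running the
inference tools is out of scope.

## Known limitations

- The event classifier is a heuristic; its scenario length upper-bounds
  but need not equal the true event count, and overlapping or
  anchor-spanning rearrangements may be merged or split.
- Cloverleaf search ranges are tuned to metazoan mitochondrial tRNAs
  (45–90 nt); exotic armless tRNAs shorter than ~45 nt return fold
  failures by design.
- The GenBank reader covers the flat-file subset mitogenome depositions
  use (CDS/tRNA/rRNA/D-loop; `complement`, origin-wrapping `join`); it
  is not a general GenBank parser.
- Composition of a region is defined over its annotated span; no
  attempt is made to resolve overlapping annotations' double-counted
  bases (the published convention).
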