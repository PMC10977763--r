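#' Genetic code with synonymous codon families
#'
#' Wraps an NCBI translation table (via Biostrings) and derives the
#' structure RSCU needs: the partition of the 64 RNA codons into
#' synonymous families (termination codons form their own family) and the
#' set of allowed initiation codons. The default, table 5 (invertebrate
#' mitochondrial), has the family structure required for mitogenome codon
#' usage: an 8-codon Ser family (UCN + AGN), UGA read as Trp, AUA as Met,
#' and stops {UAA, UAG}.
#'
#' @param id NCBI translation table number (default 5).
#' @return A `genetic_code`: list with `id`, `codon_to_aa` (named over the
#'   64 RNA codons), `families` (named list of codon vectors), and
#'   `start_codons`.
#' @examples
#' code <- genetic_code(5)
#' length(code$families$S)  # 8
#' @export
genetic_code <- function(id = 5) {
  tab <- Biostrings::getGeneticCode(as.character(id), full.search = TRUE)
  codons <- chartr("T", "U", names(tab))
  aa <- unname(tab)
  codon_to_aa <- stats::setNames(aa, codons)
  families <- split(codons, aa)
  starts <- attr(tab, "alt_init_codons")
  start_codons <- unique(c("AUG", chartr("T", "U", starts %||% character())))
  structure(
    list(id = id, codon_to_aa = codon_to_aa, families = families,
         start_codons = start_codons),
    class = "genetic_code"
  )
}

#' Extract the in-frame coding sequence of a protein-coding gene
#'
#' Returns the sense-strand CDS: L-strand genes are reverse-complemented,
#' and genes spanning the origin are stitched across it. A length not
#' divisible by 3 triggers a warning and the trailing remainder is
#' dropped (flagged via attribute `"trimmed"`).
#'
#' @param annotation A [mito_annotation()] with a sequence.
#' @param gene Name of a PCG in the annotation.
#' @return In-frame DNA string.
#' @export
extract_cds <- function(annotation, gene) {
  if (is.null(annotation$sequence)) stop("annotation carries no sequence")
  g <- annotation$genes
  i <- which(g$name == gene)
  if (!length(i)) stop("no gene named '", gene, "'")
  if (g$category[i] != "PCG") stop("'", gene, "' is not a PCG")
  s <- circular_slice(annotation$sequence, g$start[i], g$end[i])
  if (g$strand[i] == "L") s <- revcomp(s)
  rem <- nchar(s) %% 3L
  if (rem != 0L) {
    warning("CDS of ", gene, " not divisible by 3; dropping ", rem,
            " trailing nt")
    s <- substr(s, 1L, nchar(s) - rem)
    attr(s, "trimmed") <- rem
  }
  s
}

#' Start/stop codon census across the protein-coding genes
#'
#' Reads initiation and termination codons from the sequence when one is
#' present, otherwise trusts the annotation's codon columns. Codons not
#' canonical under `code` (start not an allowed initiation codon; stop
#' not a termination codon) are flagged.
#'
#' @param annotation A [mito_annotation()].
#' @param code A [genetic_code()].
#' @return data.frame with `gene`, `start_codon`, `stop_codon`,
#'   `canonical_start`, `canonical_stop`.
#' @examples
#' ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"), 16608)
#' start_stop_census(ann)
#' @export
start_stop_census <- function(annotation, code = genetic_code(5)) {
  g <- annotation$genes[annotation$genes$category == "PCG", , drop = FALSE]
  if (nrow(g) < 13L)
    warning("only ", nrow(g), " PCGs present (13 expected)")
  use_seq <- !is.null(annotation$sequence)
  starts <- stops <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (use_seq) {
      cds <- suppressWarnings(extract_cds(annotation, g$name[i]))
      starts[i] <- substr(cds, 1, 3)
      stops[i] <- substr(cds, nchar(cds) - 2, nchar(cds))
    } else {
      starts[i] <- g$start_codon[i]
      stops[i] <- g$stop_codon[i]
    }
  }
  stop_family <- chartr("U", "T", code$families[["*"]])
  start_ok <- chartr("U", "T", code$start_codons)
  data.frame(
    gene = g$name,
    start_codon = starts,
    stop_codon = stops,
    canonical_start = starts %in% start_ok,
    canonical_stop = stops %in% stop_family,
    stringsAsFactors = FALSE
  )
}

#' Count codons in a set of in-frame coding sequences
#'
#' DNA is read as RNA codons (T mapped to U) for reporting; terminators
#' are counted like any other codon.
#'
#' @param cds_set Character vector (or list) of in-frame DNA/RNA strings,
#'   each of length divisible by 3.
#' @return Named integer vector over the observed codons.
#' @examples
#' count_codons("ATGTAA")
#' @export
count_codons <- function(cds_set) {
  cds_set <- unlist(cds_set, use.names = FALSE)
  stopifnot(is.character(cds_set))
  bad <- nchar(cds_set) %% 3L != 0L
  if (any(bad)) stop("sequence length not divisible by 3 at position ",
                     which(bad)[1])
  all_codons <- unlist(lapply(cds_set, function(s) {
    n <- nchar(s)
    if (!n) return(character())
    substring(chartr("Tt", "Uu", toupper(s)), seq(1L, n, 3L), seq(3L, n, 3L))
  }))
  tab <- table(all_codons)
  stats::setNames(as.integer(tab), names(tab))
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon *i* in synonymous family *F*,
#' `RSCU_i = count_i * |F| / sum(count_j, j in F)`: the observed count
#' relative to the expectation under uniform use within the family.
#' Families with zero total get RSCU 0 for all members and are flagged.
#'
#' @param counts Named numeric vector of codon counts (RNA or DNA
#'   alphabet; any subset of the 64 codons).
#' @param code A [genetic_code()].
#' @return A `codon_usage_table`: data.frame with `codon`, `aa`, `count`,
#'   `rscu`, `per_thousand`, plus attributes `code_id` and
#'   `empty_families`.
#' @examples
#' rscu(c(GCU = 84, GCC = 19, GCA = 41, GCG = 15))
#' @export
rscu <- function(counts, code = genetic_code(5)) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0)) stop("negative codon count")
  nm <- chartr("Tt", "Uu", toupper(names(counts)))
  if (anyDuplicated(nm)) stop("duplicate codons in counts")
  full <- stats::setNames(numeric(length(code$codon_to_aa)),
                          names(code$codon_to_aa))
  unknown <- setdiff(nm, names(full))
  if (length(unknown)) stop("not codons: ", paste(unknown, collapse = ", "))
  full[nm] <- counts
  rscu_vals <- stats::setNames(numeric(length(full)), names(full))
  empty <- character()
  for (fam_aa in names(code$families)) {
    fam <- code$families[[fam_aa]]
    tot <- sum(full[fam])
    if (tot > 0) {
      rscu_vals[fam] <- full[fam] * length(fam) / tot
    } else {
      rscu_vals[fam] <- 0
      empty <- c(empty, fam_aa)
    }
  }
  total <- sum(full)
  out <- data.frame(
    codon = names(full),
    aa = unname(code$codon_to_aa),
    count = unname(full),
    rscu = unname(rscu_vals),
    per_thousand = if (total > 0) unname(1000 * full / total) else NA_real_,
    stringsAsFactors = FALSE
  )
  attr(out, "code_id") <- code$id
  attr(out, "empty_families") <- empty
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Codon incidence per thousand codons
#'
#' @param counts Named numeric vector of codon counts with positive total.
#' @return Named numeric vector: `1000 * count / total`.
#' @export
codons_per_thousand <- function(counts) {
  stopifnot(is.numeric(counts))
  total <- sum(counts)
  if (!length(counts) || total <= 0) stop("empty codon counts")
  1000 * counts / total
}

#' Codon usage for the protein-coding genes of an annotation
#'
#' Convenience wrapper: extracts every PCG's CDS, pools codon counts, and
#' computes RSCU.
#'
#' @param annotation A [mito_annotation()] with sequence.
#' @param code A [genetic_code()].
#' @return A `codon_usage_table` (see [rscu()]).
#' @export
codon_usage <- function(annotation, code = genetic_code(5)) {
  pcgs <- annotation$genes$name[annotation$genes$category == "PCG"]
  if (!length(pcgs)) stop("no PCGs in annotation")
  cds <- vapply(pcgs, function(g)
    suppressWarnings(extract_cds(annotation, g)), character(1))
  rscu(count_codons(cds), code)
}

#' Write a codon usage table as TSV
#'
#' Counts printed at one decimal and RSCU at two, matching the
#' conventional codon/count/RSCU report layout.
#'
#' @param cut A `codon_usage_table` from [rscu()].
#' @param path Output path, or `NULL` to return text.
#' @return TSV text, invisibly when written.
#' @export
write_codon_usage_tsv <- function(cut, path = NULL) {
  txt <- c("codon\taa\tcount\trscu\tper_thousand",
           sprintf("%s\t%s\t%.1f\t%.2f\t%.2f", cut$codon, cut$aa,
                   cut$count, cut$rscu, cut$per_thousand))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
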