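# Supermatrix assembly for 13-PCG phylogenetics. Alignment itself is an
# input (any aligner's FASTA output); this module concatenates per-gene
# alignments in a fixed canonical order, tracks partitions, and emits the
# text artifacts downstream inference tools consume.

.canonical_pcg_order <- c("COX1", "COX2", "COX3", "ATP6", "ATP8",
                          "NAD1", "NAD2", "NAD3", "NAD4", "NAD5", "NAD6",
                          "NAD4L", "CYTB")

#' Build a concatenated multi-gene supermatrix
#'
#' Concatenates per-gene alignments in the canonical PCG order (COX1,
#' COX2, COX3, ATP6, ATP8, NAD1-6, NAD4L, CYTB; genes not in that list
#' follow alphabetically). Taxa missing a gene are filled with the gap
#' character for that block and flagged.
#'
#' @param alignments Named list (gene -> alignment). Each alignment is a
#'   named character vector of equal-length aligned sequences, or a path
#'   to an aligned FASTA file.
#' @param gap Fill character for missing taxa (default `"-"`).
#' @return A `supermatrix`: list with `taxa`, `sequences` (named
#'   concatenated strings), `partitions` (data.frame `gene`, `start`,
#'   `end`), and `missing` (logical taxa x gene matrix).
#' @examples
#' sm <- build_supermatrix(list(
#'   COX1 = c(t1 = "ATGATG", t2 = "ATGATC"),
#'   CYTB = c(t1 = "ATGCATGCA", t2 = "ATGCATGCT")))
#' sm$partitions
#' @export
build_supermatrix <- function(alignments, gap = "-") {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  alignments <- lapply(alignments, function(a) {
    if (is.character(a) && length(a) == 1L && file.exists(a))
      a <- read_fasta(a)
    stopifnot(is.character(a), !is.null(names(a)))
    a
  })
  names(alignments) <- as.character(normalize_gene_name(names(alignments)))
  gene_names <- names(alignments)
  ordered <- c(intersect(.canonical_pcg_order, gene_names),
               sort(setdiff(gene_names, .canonical_pcg_order)))
  widths <- integer(length(ordered))
  for (k in seq_along(ordered)) {
    a <- alignments[[ordered[k]]]
    w <- unique(nchar(a))
    if (length(w) != 1L)
      stop("ragged alignment for gene ", ordered[k],
           " (row lengths ", paste(sort(w), collapse = ", "), ")")
    widths[k] <- w
  }
  taxa <- sort(unique(unlist(lapply(alignments, names))))
  if (!length(taxa)) stop("no taxa in input alignments")
  missing <- matrix(FALSE, length(taxa), length(ordered),
                    dimnames = list(taxa, ordered))
  blocks <- lapply(seq_along(ordered), function(k) {
    a <- alignments[[ordered[k]]]
    out <- stats::setNames(rep(strrep(gap, widths[k]), length(taxa)), taxa)
    out[names(a)] <- unname(a)
    missing[, k] <<- !(taxa %in% names(a))
    out
  })
  sequences <- stats::setNames(
    do.call(paste0, blocks), taxa)
  ends <- cumsum(widths)
  partitions <- data.frame(gene = ordered,
                           start = c(1L, utils::head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  structure(list(taxa = taxa, sequences = sequences,
                 partitions = partitions, missing = missing, gap = gap),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), nchar(x$sequences[[1]]),
              nrow(x$partitions)))
  invisible(x)
}

#' Read / write aligned FASTA
#'
#' Minimal FASTA support for alignment round-trips; sequences returned as
#' a named character vector.
#'
#' @param path FASTA file path.
#' @return [read_fasta()]: named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), path)
  invisible(path)
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' @param sm A [build_supermatrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  out <- c(sprintf("%d %d", length(sm$taxa), nchar(sm$sequences[[1]])),
           sprintf("%s  %s", sm$taxa, unname(sm$sequences)))
  writeLines(out, path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path PHYLIP file (sequential, one line per taxon).
#' @return Named character vector of sequences.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[!is_blank(lines)]
  body <- lines[-1]
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  stats::setNames(vapply(parts, `[[`, character(1), 3L),
                  vapply(parts, `[[`, character(1), 2L))
}

#' Write a supermatrix as NEXUS with a sets block
#'
#' Emits a `DATA` block plus a `SETS` block with one `charset` per gene
#' partition. Byte-stable (no timestamps).
#'
#' @param sm A [build_supermatrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path) {
  out <- c(
    "#NEXUS", "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
            nchar(sm$sequences[[1]])),
    sprintf("  FORMAT DATATYPE=DNA MISSING=? GAP=%s;", sm$gap),
    "  MATRIX",
    sprintf("    %s  %s", sm$taxa, unname(sm$sequences)),
    "  ;", "END;", "",
    "BEGIN SETS;",
    sprintf("  charset %s = %d-%d;", sm$partitions$gene,
            sm$partitions$start, sm$partitions$end),
    "END;"
  )
  writeLines(out, path)
  invisible(path)
}

#' Read the matrix back from a NEXUS file written by [write_nexus()]
#'
#' @param path NEXUS file path.
#' @return Named character vector of sequences.
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", lines)[1]
  i1 <- grep("^\\s*;\\s*$", lines)
  i1 <- i1[i1 > i0][1]
  body <- trimws(lines[(i0 + 1L):(i1 - 1L)])
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  stats::setNames(vapply(parts, `[[`, character(1), 3L),
                  vapply(parts, `[[`, character(1), 2L))
}

#' Emit partition and inference-configuration files
#'
#' Writes the text artifacts for external tree inference over a
#' partitioned supermatrix: (a) an IQ-TREE/RAxML-style partition file
#' assigning `GTR+F+R6` to every partition, with the ultrafast-bootstrap
#' replicate setting recorded in a comment; and (b) a MrBayes command
#' block (`nst=6`, `rates=invgamma`, 2,000,000 generations, sample
#' frequency 1000, burn-in fraction 0.25, two runs). Running the
#' inference tools is out of scope; the outputs are literal text
#' artifacts, byte-identical across runs.
#'
#' @param sm A [build_supermatrix()] result.
#' @param dir Output directory.
#' @param outgroup Optional character vector of outgroup taxa written
#'   into the MrBayes block.
#' @param model Substitution model label for the partition file.
#' @param bootstrap Ultrafast bootstrap replicate count recorded.
#' @param ngen,samplefreq,burninfrac,nruns MrBayes MCMC settings.
#' @param merge_partitions If `TRUE`, a single partition spanning the
#'   whole matrix is written instead of per-gene partitions.
#' @return Named vector of the two written paths, invisibly.
#' @export
write_inference_configs <- function(sm, dir, outgroup = NULL,
                                    model = "GTR+F+R6", bootstrap = 1000L,
                                    ngen = 2000000L, samplefreq = 1000L,
                                    burninfrac = 0.25, nruns = 2L,
                                    merge_partitions = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- if (merge_partitions) {
    data.frame(gene = "all", start = 1L,
               end = nchar(sm$sequences[[1]]), stringsAsFactors = FALSE)
  } else sm$partitions
  part_path <- file.path(dir, "partitions.txt")
  writeLines(c(
    sprintf("# ultrafast bootstrap replicates: %d", bootstrap),
    sprintf("%s, %s = %d-%d", model, parts$gene, parts$start, parts$end)
  ), part_path)
  mb_path <- file.path(dir, "mrbayes.nex")
  charsets <- sprintf("  charset %s = %d-%d;", parts$gene, parts$start,
                      parts$end)
  out <- c(
    "#NEXUS", "",
    "begin mrbayes;",
    charsets,
    sprintf("  partition bygene = %d: %s;", nrow(parts),
            paste(parts$gene, collapse = ", ")),
    "  set partition = bygene;",
    if (!is.null(outgroup))
      sprintf("  outgroup %s;", paste(outgroup, collapse = " ")),
    "  lset applyto=(all) nst=6 rates=invgamma;",
    sprintf("  mcmc ngen=%d samplefreq=%d nruns=%d burninfrac=%.2f;",
            ngen, samplefreq, nruns, burninfrac),
    "  sump;", "  sumt;",
    "end;"
  )
  writeLines(out, mb_path)
  invisible(c(partitions = part_path, mrbayes = mb_path))
}
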