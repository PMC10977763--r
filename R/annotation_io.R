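#' Construct a mitogenome annotation object
#'
#' A `mito_annotation` holds a circular genome's length, its ordered gene
#' records, and optionally the genome sequence. Coordinates are 1-based
#' inclusive; a gene whose `end` is smaller than its `start` wraps through
#' the origin. Genes are sorted by `(start, -length)` so that nested or
#' same-start genes have a deterministic order.
#'
#' @param genes A data.frame with columns `name`, `category` (PCG/tRNA/rRNA),
#'   `strand` (H/L), `start`, `end`, `length`, `start_codon`, `stop_codon`,
#'   `anticodon` (codon columns `NA` where absent).
#' @param genome_length Genome length in nt.
#' @param sequence Optional genome sequence (plain character, forward/H
#'   strand), length must equal `genome_length`.
#' @param circular Logical; mitogenomes are circular.
#' @return An object of class `mito_annotation`.
#' @export
mito_annotation <- function(genes, genome_length, sequence = NULL,
                            circular = TRUE) {
  stopifnot(is.data.frame(genes), genome_length >= 1)
  needed <- c("name", "category", "strand", "start", "end", "length",
              "start_codon", "stop_codon", "anticodon")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols))
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  genes <- genes[, needed]
  for (col in c("start", "end", "length"))
    genes[[col]] <- as.integer(genes[[col]])
  if (nrow(genes)) {
    if (anyDuplicated(genes$name))
      stop("duplicate gene names after normalization: ",
           paste(unique(genes$name[duplicated(genes$name)]), collapse = ", "))
    bad <- genes$start < 1 | genes$start > genome_length |
      genes$end < 1 | genes$end > genome_length
    if (any(bad))
      stop("coordinates outside 1..genome_length for: ",
           paste(genes$name[bad], collapse = ", "))
    expect_len <- mapply(circular_span_length, genes$start, genes$end,
                         MoreArgs = list(genome_length = genome_length))
    if (any(genes$length != expect_len)) {
      off <- genes$name[genes$length != expect_len]
      warning("printed length disagrees with coordinates for ",
              paste(off, collapse = ", "),
              "; coordinates taken as authoritative")
      genes$length <- as.integer(expect_len)
    }
    ord <- order(genes$start, -genes$length)
    genes <- genes[ord, , drop = FALSE]
    rownames(genes) <- NULL
    ties <- duplicated(genes$start)
    if (any(ties))
      attr(genes, "start_ties") <- genes$name[ties]
  }
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length)
      stop("sequence length (", nchar(sequence),
           ") != genome_length (", genome_length, ")")
  }
  structure(
    list(genome_length = as.integer(genome_length),
         circular = isTRUE(circular),
         genes = genes,
         sequence = sequence),
    class = "mito_annotation"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("mito_annotation: %d nt %s, %d genes%s\n",
              x$genome_length, if (x$circular) "circular" else "linear",
              nrow(x$genes),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  tab <- table(factor(x$genes$category, c("PCG", "tRNA", "rRNA")))
  cat(sprintf("  %d PCG / %d tRNA / %d rRNA\n", tab["PCG"], tab["tRNA"],
              tab["rRNA"]))
  invisible(x)
}

#' Parse a tab-separated gene table into an annotation
#'
#' Reads the eight-column TSV dialect (`gene`, `strand`, `start`, `end`,
#' `length`, `start_codon`, `stop_codon`, `anticodon`; header required).
#' Gene names are normalized; the printed `length` column is cross-checked
#' against the coordinates, with discrepancies reported as warnings and
#' coordinates taken as authoritative.
#'
#' @param table A file path or a single character string of TSV text.
#' @param genome_length Genome length in nt (the wrap gap between the last
#'   and first gene is computed from it).
#' @param sequence Optional genome sequence.
#' @return A [mito_annotation()].
#' @examples
#' ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"), 16608)
#' nrow(ann$genes)
#' @export
parse_gene_table <- function(table, genome_length, sequence = NULL) {
  txt <- if (length(table) == 1L && !grepl("[\t\n]", table) &&
             file.exists(table)) {
    readLines(table)
  } else {
    unlist(strsplit(paste(table, collapse = "\n"), "\n"))
  }
  txt <- txt[!is_blank(txt)]
  if (!length(txt)) stop("empty gene table")
  header <- strsplit(txt[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("gene", "strand", "start", "end", "length",
                "start_codon", "stop_codon", "anticodon")
  if (!identical(trimws(tolower(header[seq_len(min(8, length(header)))])),
                 expected[seq_len(min(8, length(header)))]) ||
      length(header) < 5)
    stop("gene table header must be: ", paste(expected, collapse = ", "))
  rows <- lapply(seq_along(txt)[-1], function(i) {
    f <- strsplit(txt[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stop("malformed row ", i, ": '", txt[[i]], "'")
    length(f) <- 8L
    start <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    if (is.na(start) || is.na(end) || start < 1 || end < 1)
      stop("malformed row ", i, ": positions must be positive integers")
    if (start > genome_length || end > genome_length)
      stop("row ", i, " (", f[1], "): coordinate exceeds genome_length ",
           genome_length)
    data.frame(
      name = trimws(f[1]), strand = trimws(f[2]),
      start = start, end = end,
      length = suppressWarnings(as.integer(f[5])),
      start_codon = toupper(trimws(f[6])),
      stop_codon = toupper(trimws(f[7])),
      anticodon = toupper(trimws(f[8])),
      stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, rows)
  if (!all(genes$strand %in% c("H", "L")))
    stop("strand column must be H or L")
  norm <- normalize_gene_name(genes$name)
  if (any(attr(norm, "unknown")))
    warning("unrecognized gene labels kept as-is: ",
            paste(genes$name[attr(norm, "unknown")], collapse = ", "))
  genes$name <- as.character(norm)
  genes$category <- gene_category(genes$name)
  for (col in c("start_codon", "stop_codon", "anticodon"))
    genes[[col]][is_blank(genes[[col]])] <- NA_character_
  coord_len <- mapply(circular_span_length, genes$start, genes$end,
                      MoreArgs = list(genome_length = genome_length))
  genes$length[is.na(genes$length)] <- coord_len[is.na(genes$length)]
  mito_annotation(genes, genome_length, sequence = sequence)
}

#' Write an annotation back to the gene-table TSV dialect
#'
#' @param annotation A [mito_annotation()].
#' @param path Output file path, or `NULL` to return the TSV text.
#' @return The TSV text, invisibly when written to a file.
#' @export
write_gene_table <- function(annotation, path = NULL) {
  g <- annotation$genes
  chr <- function(x) ifelse(is.na(x), "", as.character(x))
  body <- paste(chr(g$name), chr(g$strand), chr(g$start), chr(g$end),
                chr(g$length), chr(g$start_codon), chr(g$stop_codon),
                chr(g$anticodon), sep = "\t")
  txt <- c(paste(c("gene", "strand", "start", "end", "length",
                   "start_codon", "stop_codon", "anticodon"),
                 collapse = "\t"), body)
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Intergenic spacers and gene overlaps on a circular annotation
#'
#' For every pair of consecutive genes (sorted by start, plus the circular
#' wrap pair from the last gene back to the first) the gap is
#' `next_start - prev_end - 1`; the wrap pair adds the genome length.
#' Positive gaps are intergenic spacers, zero gaps abutments, negative gaps
#' overlaps of `|gap|` nt.
#'
#' @param annotation A [mito_annotation()] with at least 2 genes.
#' @return A `spacer_report`: list with `pairs` (data.frame `upstream`,
#'   `downstream`, `gap`), `overlaps`, `spacers`, `abutments` subsets,
#'   `max_spacer`, and counts.
#' @examples
#' ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"), 16608)
#' rep <- spacers_and_overlaps(ann)
#' rep$overlaps
#' @export
spacers_and_overlaps <- function(annotation) {
  g <- annotation$genes
  if (nrow(g) < 2L) stop("need at least 2 genes")
  n <- nrow(g)
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    gap[i] <- if (j == 1L) {
      annotation$genome_length - g$end[i] + g$start[j] - 1L
    } else {
      g$start[j] - g$end[i] - 1L
    }
  }
  pairs <- data.frame(upstream = g$name, downstream = g$name[nxt],
                      gap = gap, stringsAsFactors = FALSE)
  structure(
    list(pairs = pairs,
         overlaps = pairs[pairs$gap < 0, , drop = FALSE],
         abutments = pairs[pairs$gap == 0, , drop = FALSE],
         spacers = pairs[pairs$gap > 0, , drop = FALSE],
         n_overlap = sum(gap < 0), n_abutment = sum(gap == 0),
         n_spacer = sum(gap > 0),
         max_spacer = if (any(gap > 0)) max(gap) else 0L,
         total_spacer = sum(gap[gap > 0]),
         total_overlap = sum(-gap[gap < 0])),
    class = "spacer_report"
  )
}

#' @export
print.spacer_report <- function(x, ...) {
  cat(sprintf(
    "spacer_report: %d spacers (total %d nt, max %d), %d abutments, %d overlaps (total %d nt)\n",
    x$n_spacer, x$total_spacer, x$max_spacer, x$n_abutment, x$n_overlap,
    x$total_overlap))
  invisible(x)
}

#' Gene-content census of an annotation
#'
#' Counts per category and strand, longest and shortest genes, summed
#' lengths per category, and the list of L-strand genes.
#'
#' @param annotation A nonempty [mito_annotation()].
#' @return A list of class `mito_census`.
#' @examples
#' ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"), 16608)
#' census(ann)
#' @export
census <- function(annotation) {
  g <- annotation$genes
  if (!nrow(g)) stop("empty annotation")
  cat_counts <- table(factor(g$category, c("PCG", "tRNA", "rRNA")))
  strand_counts <- table(factor(g$strand, c("H", "L")))
  longest <- g[which.max(g$length), ]
  shortest <- g[which.min(g$length), ]
  structure(
    list(
      n_genes = nrow(g),
      by_category = stats::setNames(as.list(as.integer(cat_counts)),
                                    names(cat_counts)),
      by_strand = stats::setNames(as.list(as.integer(strand_counts)),
                                  names(strand_counts)),
      longest_gene = longest$name, longest_length = longest$length,
      shortest_gene = shortest$name, shortest_length = shortest$length,
      length_by_category = lapply(
        split(g$length, factor(g$category, c("PCG", "tRNA", "rRNA"))), sum),
      l_strand_genes = g$name[g$strand == "L"]
    ),
    class = "mito_census"
  )
}

#' @export
print.mito_census <- function(x, ...) {
  cat(sprintf("mito_census: %d genes (%d PCG / %d tRNA / %d rRNA)\n",
              x$n_genes, x$by_category$PCG, x$by_category$tRNA,
              x$by_category$rRNA))
  cat(sprintf("  longest %s (%d nt), shortest %s (%d nt)\n",
              x$longest_gene, x$longest_length, x$shortest_gene,
              x$shortest_length))
  cat(sprintf("  L-strand genes: %s\n",
              paste(x$l_strand_genes, collapse = ", ")))
  invisible(x)
}

#' Write a census as JSON
#'
#' @param cen A `mito_census` from [census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_json <- function(cen, path) {
  jsonlite::write_json(unclass(cen), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
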