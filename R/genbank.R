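# Minimal GenBank flat-file support for circular mitogenomes. Only the
# feature types a mitogenome annotation uses (CDS, tRNA, rRNA, D-loop) are
# mapped; everything else is skipped with a warning. Locations understood:
# `a..b`, `complement(a..b)`, `join(a..N,1..b)` (origin wrap) and
# `complement(join(...))`.

#' Parse a GenBank flat file into a mitogenome annotation
#'
#' @param file Path to a GenBank flat file with a `LOCUS` line, a
#'   `FEATURES` table, and optionally an `ORIGIN` sequence block.
#' @return A [mito_annotation()]; complement-strand features get strand
#'   `L`, `/anticodon` and `/codon_start` qualifiers are honored, and
#'   start/stop codons are read off the sequence when present.
#' @export
parse_genbank <- function(file) {
  lines <- readLines(file)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  m <- regmatches(locus[1], regexec("([0-9]+)\\s+bp", locus[1]))[[1]]
  if (length(m) < 2) stop("LOCUS line lacks a sequence length")
  genome_length <- as.integer(m[2])
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  feat_start <- grep("^FEATURES", lines)
  seq_start <- grep("^ORIGIN", lines)
  feat_end <- if (length(seq_start)) seq_start[1] - 1L else length(lines)
  feats <- if (length(feat_start)) lines[(feat_start[1] + 1L):feat_end]
           else character()

  # Fold continuation lines into single feature entries.
  entries <- list()
  cur <- NULL
  for (ln in feats) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      cur <- ln
    } else if (!is.null(cur)) {
      cur <- paste0(cur, "\n", ln)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  sequence <- NULL
  if (length(seq_start)) {
    seq_lines <- lines[(seq_start[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nchar(sequence)) sequence <- NULL
  }

  rows <- list()
  for (e in entries) {
    first <- strsplit(e, "\n", fixed = TRUE)[[1]][1]
    type <- sub("^\\s*(\\S+).*$", "\\1", first)
    if (type == "source") next
    if (!type %in% c("CDS", "tRNA", "rRNA", "D-loop")) {
      warning("ignoring feature of type '", type, "'")
      next
    }
    if (type == "D-loop") next  # non-gene region, not a GeneRecord
    loc <- sub("^\\s*\\S+\\s+", "", first)
    p <- .parse_location(loc)
    quals <- .parse_qualifiers(e)
    name <- quals[["gene"]] %||% quals[["product"]] %||% NA_character_
    if (is.na(name)) {
      warning("feature without /gene or /product skipped: ", first)
      next
    }
    codon_start <- as.integer(quals[["codon_start"]] %||% "1")
    start_codon <- stop_codon <- NA_character_
    if (type == "CDS" && !is.null(sequence)) {
      cds <- circular_slice(sequence, p$start, p$end)
      if (p$strand == "L") cds <- revcomp(cds)
      if (codon_start > 1L) cds <- substr(cds, codon_start, nchar(cds))
      start_codon <- substr(cds, 1, 3)
      stop_codon <- substr(cds, nchar(cds) - 2, nchar(cds))
    }
    anticodon <- quals[["anticodon"]]
    if (!is.null(anticodon)) {
      # accept either a bare triplet or the (pos:..,aa:..,seq:nnn) form
      sm <- regmatches(anticodon, regexec("seq:([A-Za-z]{3})", anticodon))[[1]]
      anticodon <- toupper(if (length(sm) == 2) sm[2] else anticodon)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, strand = p$strand, start = p$start, end = p$end,
      length = circular_span_length(p$start, p$end, genome_length),
      start_codon = start_codon, stop_codon = stop_codon,
      anticodon = anticodon %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    warning("GenBank file contains no gene features")
    genes <- data.frame(name = character(), category = character(),
                        strand = character(), start = integer(),
                        end = integer(), length = integer(),
                        start_codon = character(), stop_codon = character(),
                        anticodon = character(), stringsAsFactors = FALSE)
    return(mito_annotation(genes, genome_length, sequence = sequence,
                           circular = circular))
  }
  genes <- do.call(rbind, rows)
  genes$name <- as.character(normalize_gene_name(genes$name))
  genes$category <- gene_category(genes$name)
  mito_annotation(genes, genome_length, sequence = sequence,
                  circular = circular)
}

.parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    spans <- lapply(parts, .parse_span)
    # origin wrap: first span runs to the genome end, second from 1
    start <- spans[[1]]$start
    end <- spans[[length(spans)]]$end
  } else {
    sp <- .parse_span(loc)
    start <- sp$start
    end <- sp$end
  }
  list(start = start, end = end, strand = strand)
}

.parse_span <- function(x) {
  m <- regmatches(x, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", x))[[1]]
  if (length(m) != 3) stop("unsupported location: '", x, "'")
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

.parse_qualifiers <- function(entry) {
  qlines <- regmatches(entry,
                       gregexpr("/[A-Za-z_]+=(\"[^\"]*\"|[^[:space:]]+)",
                                entry))[[1]]
  quals <- list()
  for (q in qlines) {
    key <- sub("^/([A-Za-z_]+)=.*$", "\\1", q)
    val <- sub("^/[A-Za-z_]+=", "", q)
    val <- gsub("^\"|\"$", "", val)
    quals[[key]] <- val
  }
  quals
}

#' Write a mitogenome annotation as a GenBank flat file
#'
#' Emits a minimal flat file (LOCUS, FEATURES, ORIGIN when a sequence is
#' present) that [parse_genbank()] reads back to an identical annotation.
#' No timestamps are written, so output is byte-stable.
#'
#' @param annotation A [mito_annotation()].
#' @param path Output file path.
#' @param accession Locus name to print.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(annotation, path, accession = "SYNMITO") {
  g <- annotation$genes
  out <- c(sprintf("LOCUS       %-12s %d bp    DNA     %s   UNA",
                   accession, annotation$genome_length,
                   if (annotation$circular) "circular" else "linear"),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", annotation$genome_length))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    span <- if (r$end >= r$start) {
      sprintf("%d..%d", r$start, r$end)
    } else {
      sprintf("join(%d..%d,1..%d)", r$start, annotation$genome_length, r$end)
    }
    if (r$strand == "L") span <- sprintf("complement(%s)", span)
    type <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")[[r$category]]
    out <- c(out, sprintf("     %-15s %s", type, span),
             sprintf("                     /gene=\"%s\"", r$name))
    if (!is.na(r$anticodon))
      out <- c(out, sprintf("                     /anticodon=\"%s\"",
                            r$anticodon))
    if (r$category == "PCG")
      out <- c(out, "                     /codon_start=1")
  }
  if (!is.null(annotation$sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(annotation$sequence)
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
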