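# Seed-controlled synthetic mitogenomes. The generator emulates the
# statistical structure the analysis assumes: a circular AT-rich
# (~70% A+T) genome of roughly 15-17 kb carrying 13 PCGs, 22 tRNAs and 2
# rRNAs; PCGs are open reading frames under the invertebrate
# mitochondrial code with configured start/stop codons and no internal
# terminators; tRNA genes are instantiated from cloverleaf templates with
# known ground-truth layouts; rRNAs and spacers are random AT-rich
# sequence. Everything is reproducible from (spec, seed).

.default_anticodons <- c(
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnD = "GTC", trnC = "GCA",
  trnQ = "TTG", trnE = "TTC", trnG = "TCC", trnH = "GTG", trnI = "GAT",
  trnK = "TTT", trnL1 = "TAG", trnL2 = "TAA", trnM = "CAT", trnF = "GAA",
  trnP = "TGG", trnS1 = "GCT", trnS2 = "TGA", trnT = "TGT", trnW = "TCA",
  trnY = "GTA", trnV = "TAC"
)

.default_pcg_lengths <- c(
  COX1 = 1551, COX2 = 693, COX3 = 780, ATP6 = 696, ATP8 = 159,
  NAD1 = 945, NAD2 = 1089, NAD3 = 357, NAD4 = 1305, NAD4L = 303,
  NAD5 = 1872, NAD6 = 504, CYTB = 1140
)

.default_rrna_lengths <- c(rrnL = 1364, rrnS = 896)

.random_bases <- function(n, at) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

#' Generate a template tRNA with known cloverleaf layout
#'
#' Builds a tRNA sequence by reverse-complement stem construction:
#' acceptor and anticodon arms are always present; the D and/or T arm can
#' be omitted (replaced by an unstructured span), emulating the
#' degenerate D-armless serine and T-armless alanine tRNAs of many
#' invertebrate mitogenomes. Wobble pairs or mismatches can be injected
#' into the acceptor stem at configured pair positions.
#'
#' @param arm_config Subset of `c("acceptor", "D", "anticodon", "T")`;
#'   acceptor and anticodon arms are mandatory.
#' @param anticodon 3-mer DNA anticodon placed centrally in the anticodon
#'   loop.
#' @param seed Integer seed; fixed seed gives a bit-identical sequence.
#' @param at AT fraction for loop/link sequence.
#' @param mismatch_at,wobble_at Integer vectors of acceptor-stem pair
#'   indices (1 = outermost) to turn into mismatches / G·U wobbles.
#' @return List with `seq` (DNA string) and `truth` (arm presence flags,
#'   anticodon, segment coordinates).
#' @examples
#' tr <- generate_trna(anticodon = "GCA", seed = 42)
#' nchar(tr$seq)
#' @export
generate_trna <- function(arm_config = c("acceptor", "D", "anticodon", "T"),
                          anticodon = "TGC", seed = NULL, at = 0.7,
                          mismatch_at = integer(), wobble_at = integer()) {
  stopifnot(all(c("acceptor", "anticodon") %in% arm_config))
  anticodon <- toupper(chartr("U", "T", anticodon))
  stopifnot(nchar(anticodon) == 3L)
  with_seed(seed, {
    rb <- function(n) .random_bases(n, at)
    # stems follow the genome AT target: reverse-complement construction
    # keeps the stem's AT fraction equal to its template's
    stem <- function(n) .random_bases(n, at)
    acc5 <- stem(7L)
    if (length(wobble_at)) {
      a <- strsplit(acc5, "")[[1]]
      a[wobble_at] <- "G"          # G on the 5' side...
      acc5 <- paste(a, collapse = "")
    }
    acc3 <- revcomp(acc5)
    if (length(wobble_at)) {
      a <- strsplit(acc3, "")[[1]]
      a[8L - wobble_at] <- "T"     # ...pairs T on the 3' side: G-T wobble
      acc3 <- paste(a, collapse = "")
    }
    if (length(mismatch_at)) {
      a5 <- strsplit(acc5, "")[[1]]
      a3 <- strsplit(acc3, "")[[1]]
      for (k in mismatch_at) {
        b <- a5[k]
        partner <- c(A = "T", T = "A", G = "C", C = "G")[[b]]
        bad <- setdiff(c("A", "C", "G", "T"), partner)
        if (b == "G") bad <- setdiff(bad, "T")
        if (b == "T") bad <- setdiff(bad, "G")
        a3[8L - k] <- sample(bad, 1L)
      }
      acc3 <- paste(a3, collapse = "")
    }
    link1 <- rb(2L)
    ac5 <- stem(5L)
    if ("D" %in% arm_config) {
      d5 <- stem(4L); dloop <- rb(8L)
      d_part <- paste0(d5, dloop, revcomp(d5))
      link2 <- rb(1L)
    } else {
      # Unstructured span in place of the D arm: redrawn until it truly
      # contains no acceptable stem, so the D-less label is ground truth.
      # The window includes the anticodon stem's first base, which a
      # shortened (4 bp) anticodon stem would cede to the D region.
      repeat {
        d_part <- rb(8L)
        link2 <- rb(1L)
        if (!.has_spurious_stem(paste0(link1, d_part, link2,
                                       substr(ac5, 1L, 1L)))) break
      }
    }
    acloop <- paste0(rb(2L), anticodon, rb(2L))
    ac_part <- paste0(ac5, acloop, revcomp(ac5))
    var <- rb(4L)
    t_part <- if ("T" %in% arm_config) {
      t5 <- stem(5L)
      paste0(t5, rb(7L), revcomp(t5))
    } else ""
    disc <- rb(1L)
    seq <- paste0(acc5, link1, d_part, link2, ac_part, var, t_part, acc3,
                  disc)
    list(
      seq = seq,
      truth = list(
        arm_present = c(acceptor = TRUE, D = "D" %in% arm_config,
                        anticodon = TRUE, T = "T" %in% arm_config),
        anticodon = anticodon,
        length = nchar(seq),
        n_mismatch = length(mismatch_at),
        n_wobble = length(wobble_at)
      )
    )
  })
}

#' Specification for a synthetic mitogenome
#'
#' The defaults emulate the study conditions for a gastropod-like
#' mitogenome: ~16.6 kb, 70% A+T, the 37-gene complement laid out in the
#' packaged gene order, D-armless trnS1/trnS2 and T-armless trnA, a
#' single large non-coding region (control-region analog) after trnF, and
#' small random spacers elsewhere.
#'
#' @param genome_length Target genome length (nt); trailing non-coding
#'   sequence pads to it.
#' @param at_content Target A+T fraction in (0, 1).
#' @param order A [gene_order()], or `NULL` for the packaged 37-gene
#'   order.
#' @param pcg_lengths,rrna_lengths Named overrides of gene lengths.
#' @param start_codon,stop_codon Start/stop codon policy: a single codon
#'   applied to every PCG, or a named vector of per-gene codons.
#' @param spacer_range Range (min, max) of random intergenic spacers.
#' @param cr_after Gene after which the large non-coding region sits.
#' @param cr_length Its length (nt).
#' @param armless Named list mapping tRNA labels to their arm
#'   configuration (defaults: trnS1/trnS2 without D arm, trnA without T
#'   arm).
#' @param seed Integer seed; fixed (spec, seed) reproduces the genome
#'   bit-identically.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_length = 16608L, at_content = 0.70,
                        order = NULL,
                        pcg_lengths = .default_pcg_lengths,
                        rrna_lengths = .default_rrna_lengths,
                        start_codon = "ATG", stop_codon = "TAA",
                        spacer_range = c(0L, 20L),
                        cr_after = "trnF", cr_length = 648L,
                        armless = list(trnS1 = c("acceptor", "anticodon", "T"),
                                       trnS2 = c("acceptor", "anticodon", "T"),
                                       trnA = c("acceptor", "D", "anticodon")),
                        seed = 1L) {
  stopifnot(at_content > 0, at_content < 1, genome_length > 0)
  if (is.null(order)) {
    ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"),
                            genome_length = 16608L)
    order <- order_from_annotation(ann)
  }
  structure(
    list(genome_length = as.integer(genome_length),
         at_content = at_content, order = order,
         pcg_lengths = pcg_lengths, rrna_lengths = rrna_lengths,
         start_codon = start_codon, stop_codon = stop_codon,
         spacer_range = as.integer(spacer_range),
         cr_after = cr_after, cr_length = as.integer(cr_length),
         armless = armless, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# TRUE when any D-stem-sized placement inside `window` pairs acceptably
# (>= min_pairs positions Watson-Crick or G.U with positive score).
.has_spurious_stem <- function(window, stems = 3:4, loops = 4:12,
                               min_pairs = 3L) {
  ch <- strsplit(toupper(window), "")[[1]]
  n <- length(ch)
  pair_ok <- function(x, y)
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  for (s in stems) for (l in loops) {
    span <- 2L * s + l
    if (span > n) next
    for (off in 0:(n - span)) {
      hits <- sum(vapply(seq_len(s), function(k)
        pair_ok(ch[off + k], ch[off + span - k + 1L]), logical(1)))
      wc <- sum(vapply(seq_len(s), function(k) {
        p <- paste0(ch[off + k], ch[off + span - k + 1L])
        p %in% c("AT", "TA", "GC", "CG")
      }, logical(1)))
      score <- 2L * wc + (hits - wc) - 2L * (s - hits)
      if (hits >= min_pairs && score > 0L) return(TRUE)
    }
  }
  FALSE
}

.codon_pool <- function(code) {
  # DNA codons that are neither terminators nor absent from the code
  dna <- chartr("U", "T", names(code$codon_to_aa))
  dna[code$codon_to_aa != "*"]
}

.sample_codons <- function(n, at, pool) {
  # per-base categorical draws at the AT target, rejecting terminators by
  # construction (draw from the non-stop pool, weighted by base content)
  w <- vapply(pool, function(cd) {
    b <- strsplit(cd, "")[[1]]
    prod(ifelse(b %in% c("A", "T"), at / 2, (1 - at) / 2))
  }, numeric(1))
  sample(pool, n, replace = TRUE, prob = w)
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds the circular sequence and its matching annotation from a
#' [genome_spec()]. Every PCG is an open reading frame under the chosen
#' genetic code (configured start/stop codons, no internal terminators);
#' tRNAs come from [generate_trna()] templates with recorded layouts;
#' rRNAs, spacers, and the control-region analog are random AT-rich
#' sequence. L-strand genes are generated on their sense strand and
#' reverse-complemented into the genome.
#'
#' @param spec A [genome_spec()].
#' @param code A [genetic_code()].
#' @return List with `annotation` (a [mito_annotation()] carrying the
#'   sequence) and `truth` (per-gene tRNA layouts, pooled PCG codon
#'   counts, realized AT content, the spec and seed).
#' @examples
#' gen <- generate_mitogenome(genome_spec(seed = 7))
#' gen$annotation
#' @export
generate_mitogenome <- function(spec = genome_spec(),
                                code = genetic_code(5)) {
  ord <- spec$order
  n <- length(ord$labels)
  cats <- gene_category(ord$labels)
  # feasibility before any generation
  glen <- function(lbl, cat) {
    if (cat == "PCG") {
      unname(spec$pcg_lengths[lbl])
    } else if (cat == "rRNA") {
      unname(spec$rrna_lengths[lbl])
    } else {
      ac <- spec$armless[[lbl]]
      if (is.null(ac)) 72L else if (!"D" %in% ac) 64L else 55L
    }
  }
  lens <- mapply(glen, ord$labels, cats)
  if (anyNA(lens)) stop("no length configured for: ",
                        paste(ord$labels[is.na(lens)], collapse = ", "))
  min_total <- sum(lens) + spec$cr_length
  if (min_total > spec$genome_length)
    stop("infeasible spec: gene lengths + control region (", min_total,
         " nt) exceed genome_length (", spec$genome_length, ")")

  with_seed(spec$seed, {
    pool <- .codon_pool(code)
    start_of <- function(lbl) {
      if (length(spec$start_codon) == 1L && is.null(names(spec$start_codon)))
        spec$start_codon else unname(spec$start_codon[lbl])
    }
    stop_of <- function(lbl) {
      if (length(spec$stop_codon) == 1L && is.null(names(spec$stop_codon)))
        spec$stop_codon else unname(spec$stop_codon[lbl])
    }
    pieces <- character()
    rows <- list()
    truth_trna <- list()
    codon_counts_by_gene <- list()
    pos <- 1L
    budget <- spec$genome_length - min_total   # nt available for spacers
    for (i in seq_len(n)) {
      lbl <- ord$labels[i]
      cat <- cats[i]
      strand <- if (ord$sign[i] > 0) "H" else "L"
      start_codon <- stop_codon <- anticodon <- NA_character_
      if (cat == "PCG") {
        n_codons <- lens[i] / 3L
        stopifnot(n_codons == floor(n_codons))
        body <- .sample_codons(n_codons - 2L, spec$at_content, pool)
        start_codon <- start_of(lbl)
        stop_codon <- stop_of(lbl)
        sense <- paste(c(start_codon, body, stop_codon), collapse = "")
        codon_counts_by_gene[[lbl]] <-
          count_codons(sense)
      } else if (cat == "rRNA") {
        sense <- .random_bases(lens[i], spec$at_content)
      } else {
        ac <- spec$armless[[lbl]] %||% c("acceptor", "D", "anticodon", "T")
        anticodon <- unname(.default_anticodons[lbl] %||% "CAT")
        tr <- generate_trna(arm_config = ac, anticodon = anticodon,
                            seed = NULL, at = spec$at_content)
        sense <- tr$seq
        truth_trna[[lbl]] <- tr$truth
        lens[i] <- nchar(sense)
      }
      laid <- if (strand == "L") revcomp(sense) else sense
      rows[[i]] <- data.frame(
        name = lbl, category = cat, strand = strand,
        start = pos, end = pos + nchar(laid) - 1L, length = nchar(laid),
        start_codon = start_codon, stop_codon = stop_codon,
        anticodon = anticodon, stringsAsFactors = FALSE
      )
      pieces[[length(pieces) + 1L]] <- laid
      pos <- pos + nchar(laid)
      # intergenic spacer (control-region analog after the configured gene)
      gap <- if (identical(lbl, spec$cr_after)) {
        spec$cr_length
      } else if (i < n) {
        g <- sample(spec$spacer_range[1]:spec$spacer_range[2], 1L)
        g <- min(g, budget)
        budget <- budget - g
        g
      } else 0L
      if (gap > 0L) {
        pieces[[length(pieces) + 1L]] <- .random_bases(gap, spec$at_content)
        pos <- pos + gap
      }
    }
    # trailing padding to hit the target length exactly
    pad <- spec$genome_length - (pos - 1L)
    if (pad > 0L)
      pieces[[length(pieces) + 1L]] <- .random_bases(pad, spec$at_content)
    sequence <- paste(pieces, collapse = "")
    genes <- do.call(rbind, rows)
    ann <- mito_annotation(genes, spec$genome_length, sequence = sequence)
    prof <- composition_profile(sequence, "genome")
    pooled <- Reduce(function(a, b) {
      all_nm <- union(names(a), names(b))
      av <- stats::setNames(integer(length(all_nm)), all_nm)
      av[names(a)] <- av[names(a)] + a
      av[names(b)] <- av[names(b)] + b
      av
    }, codon_counts_by_gene)
    list(annotation = ann,
         truth = list(trna = truth_trna,
                      codon_counts = pooled,
                      codon_counts_by_gene = codon_counts_by_gene,
                      at_content = prof$at_content / 100,
                      spec = spec))
  })
}

#' Apply typed rearrangement events to a signed gene order
#'
#' Applies shuffling / translocation / inversion / inverted-translocation
#' events in sequence and returns the rearranged order together with the
#' exact realized event log (the ground truth for recovery tests). Events
#' may fix their block and destination, or leave them to be drawn
#' randomly under the type's constraints; randomly drawn events use
#' non-overlapping regions and never touch the anchor (first) gene.
#'
#' @param order A [gene_order()] (canonical form recommended).
#' @param events Either an integer (number of random events), a character
#'   vector of types to realize randomly, or a list of event lists with
#'   `type` and optionally `genes` (contiguous block labels) and `after`
#'   (label the moved block is inserted after).
#' @param seed Integer seed for the random draws.
#' @param types Pool of types drawn from when `events` is a count.
#' @return List with `order` (rearranged [gene_order()]) and `log` (list
#'   of realized events: `type`, `genes`, `after`).
#' @examples
#' ref <- read_gene_order(mito_example("ancestral_gastropod_order.tsv"))
#' out <- apply_rearrangements(ref, 2, seed = 1)
#' vapply(out$log, `[[`, character(1), "type")
#' @export
apply_rearrangements <- function(order, events, seed = NULL,
                                 types = c("shuffling", "translocation",
                                           "inversion",
                                           "inverted_translocation")) {
  if (is.numeric(events) && length(events) == 1L)
    events <- with_seed(seed, sample(types, events, replace = TRUE))
  if (is.character(events))
    events <- lapply(events, function(t) list(type = t))
  with_seed(seed, {
    used <- rep(FALSE, length(order$labels))
    used[1L] <- TRUE   # anchor stays put
    planned <- list()
    for (ev in events) {
      if (is.null(ev$genes)) {
        ev <- .draw_event(order, ev$type, used)
        if (is.null(ev)) stop("could not place a non-overlapping ",
                              "event; too many events for this order")
      }
      reg <- match(c(ev$genes, ev$region), order$labels)
      if (any(used[reg]) && !isTRUE(ev$allow_overlap))
        stop("event blocks overlap; pass allow_overlap = TRUE to permit")
      used[reg] <- TRUE
      planned[[length(planned) + 1L]] <- ev
    }
    cur <- order
    for (ev in planned) cur <- .apply_event(cur, ev)
    list(order = cur, log = planned)
  })
}

# Draw one random event of the given type over unused, non-anchor indices.
.draw_event <- function(order, type, used) {
  n <- length(order$labels)
  cats <- gene_category(order$labels)
  free_run_from <- function(i) {
    k <- 0L
    while (i + k <= n && !used[i + k]) k <- k + 1L
    k
  }
  for (attempt in seq_len(200L)) {
    if (type == "inversion") {
      len <- sample(1:3, 1L)
      i <- sample(seq_len(n), 1L)
      if (i + len - 1L > n || free_run_from(i) < len) next
      return(list(type = type, genes = order$labels[i:(i + len - 1L)],
                  after = NA_character_, region = character()))
    }
    if (type == "shuffling") {
      len <- sample(1:2, 1L)
      span <- sample(1:2, 1L)
      i <- sample(seq_len(n), 1L)
      j <- i + len + span - 1L
      if (j > n || free_run_from(i) < len + span) next
      idx_b <- i:(i + len - 1L)
      idx_s <- (i + len):j
      if (!all(cats[c(idx_b, idx_s)] == "tRNA")) next
      return(list(type = type, genes = order$labels[idx_b],
                  after = order$labels[j],
                  region = order$labels[idx_s]))
    }
    # translocation / inverted_translocation: block crosses a span that
    # (for plain translocation) contains a PCG or rRNA and is longer than
    # the block, so the moved material is unambiguous
    len <- sample(1:3, 1L)
    span <- sample(4:8, 1L)
    i <- sample(seq_len(n), 1L)
    j <- i + len + span - 1L
    if (j > n || free_run_from(i) < len + span) next
    idx_b <- i:(i + len - 1L)
    idx_s <- (i + len):j
    if (type == "translocation" &&
        !any(cats[idx_s] %in% c("PCG", "rRNA"))) next
    return(list(type = type, genes = order$labels[idx_b],
                after = order$labels[j],
                region = order$labels[idx_s]))
  }
  NULL
}

.apply_event <- function(order, ev) {
  idx <- match(ev$genes, order$labels)
  if (anyNA(idx)) stop("event references unknown genes: ",
                       paste(ev$genes[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (length(idx) > 1L && any(diff(idx) != 1L))
    stop("event block is not contiguous: ", paste(ev$genes, collapse = " "))
  labels <- order$labels
  sign <- order$sign
  flip <- ev$type %in% c("inversion", "inverted_translocation")
  bl <- labels[idx]
  bs <- sign[idx]
  if (flip) {
    bl <- rev(bl)
    bs <- -rev(bs)
  }
  if (ev$type == "inversion" || is.na(ev$after %||% NA)) {
    labels[idx] <- bl
    sign[idx] <- bs
    return(gene_order(labels, sign))
  }
  keep_l <- labels[-idx]
  keep_s <- sign[-idx]
  at <- match(ev$after, keep_l)
  if (is.na(at)) stop("insertion anchor not found: ", ev$after)
  gene_order(append(keep_l, bl, after = at),
             append(keep_s, bs, after = at))
}

#' Write a synthetic genome bundle to disk
#'
#' Emits the GenBank flat file, FASTA, gene-table TSV, and ground-truth
#' JSON for a generated mitogenome.
#'
#' @param gen Result of [generate_mitogenome()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named vector of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(gen, dir, name = "synthetic_mitogenome") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- gen$annotation
  paths <- c(
    genbank = file.path(dir, paste0(name, ".gb")),
    fasta = file.path(dir, paste0(name, ".fasta")),
    table = file.path(dir, paste0(name, ".tsv")),
    truth = file.path(dir, paste0(name, "_truth.json"))
  )
  write_genbank(ann, paths[["genbank"]], accession = toupper(name))
  writeLines(c(paste0(">", name), ann$sequence), paths[["fasta"]])
  write_gene_table(ann, paths[["table"]])
  truth <- gen$truth
  truth$spec$order <- NULL   # gene_order serialized separately if needed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}
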