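# Rearrangement event classification. The scenario builder is a greedy
# heuristic: it repeatedly fixes the leftmost position (in canonical form,
# anchored at COX1+) where the working copy of the reference disagrees
# with the query, by moving one contiguous block. Each move is typed with
# the field's three-category vocabulary:
#   shuffling        - block moves past tRNA genes only, same strand
#   translocation    - block moves past at least one PCG or rRNA, same strand
#   inversion        - block switches strand in place
#   inverted_translocation - block both moves and switches strand
# The scenario is not guaranteed minimal (exact multi-type rearrangement
# distances are computationally hard); the report says so.

#' Classify rearrangement events between two gene orders
#'
#' Builds a greedy block-moving scenario transforming the reference order
#' into the query order and types each move as shuffling, translocation,
#' inversion, or inverted translocation. Shuffling versus translocation is
#' decided by the genes a block traverses, measured on the (working)
#' reference: crossing only tRNAs is shuffling, crossing a PCG or rRNA is
#' translocation.
#'
#' @param query,ref [gene_order()] objects over identical label sets.
#' @param categories Optional named character vector mapping labels to
#'   `PCG`/`tRNA`/`rRNA`; by default inferred from the label (trn*/rrn*
#'   prefixes).
#' @param anchor Canonicalization anchor (kept fixed; never moved).
#' @return A `rearrangement_report`: list with `breakpoint_count`,
#'   `synteny_blocks`, `events` (each with `type`, `genes`, `flipped`,
#'   `traversed`, `description`), `differing_genes`, `n_events`, and
#'   `heuristic = TRUE`.
#' @examples
#' ref <- read_gene_order(mito_example("ancestral_gastropod_order.tsv"))
#' ann <- parse_gene_table(mito_example("desmaulus_table2.tsv"), 16608)
#' rep <- classify_events(order_from_annotation(ann), ref)
#' vapply(rep$events, `[[`, character(1), "type")
#' @export
classify_events <- function(query, ref, categories = NULL,
                            anchor = "COX1") {
  .check_same_labels(query, ref)
  if (is.null(categories))
    categories <- stats::setNames(gene_category(query$labels), query$labels)
  q <- canonicalize_gene_order(query, anchor)
  w <- canonicalize_gene_order(ref, anchor)
  bp <- breakpoints(q, w)
  blocks <- synteny_blocks(q, w)

  tl <- q$labels; ts <- q$sign
  events <- list()
  n <- length(tl)
  guard <- 0L
  repeat {
    mism <- which(w$labels != tl | w$sign != ts)
    if (!length(mism)) break
    guard <- guard + 1L
    if (guard > 2L * n) {
      warning("greedy scenario did not converge; partial event list")
      break
    }
    i <- mism[1L]
    ca <- .candidate_target_run(tl, ts, w, i)
    cb <- .candidate_working_run(tl, ts, w, i)
    use <- .pick_candidate(ca, cb, tl, ts, w)
    mv <- .apply_move(w, use)
    events[[length(events) + 1L]] <- .type_event(use, w, categories)
    w <- mv
  }

  differing <- q$labels[q$sign != canonicalize_gene_order(ref, anchor)$sign[
    match(q$labels, canonicalize_gene_order(ref, anchor)$labels)]]
  neighbor_diff <- unique(unlist(lapply(
    blocks[!vapply(blocks, function(b)
      length(b$labels) == length(tl) && b$direction == "forward",
      logical(1))],
    function(b) if (length(blocks) > 1L) b$labels else character())))
  structure(
    list(breakpoint_count = bp$count,
         synteny_blocks = blocks,
         events = events,
         n_events = length(events),
         differing_genes = sort(unique(c(differing, neighbor_diff))),
         heuristic = TRUE),
    class = "rearrangement_report"
  )
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf(
    "rearrangement_report: %d breakpoints, %d synteny blocks, %d events (greedy, not necessarily minimal)\n",
    x$breakpoint_count, length(x$synteny_blocks), x$n_events))
  for (e in x$events) cat("  -", e$description, "\n")
  invisible(x)
}

.flip_signed <- function(labels, sign) {
  list(labels = rev(labels), sign = -rev(sign))
}

# Candidate (a): the longest run of the target starting at position i that
# sits contiguously in w, forward (same signs) or reversed-with-flip.
.candidate_target_run <- function(tl, ts, w, i) {
  n <- length(tl)
  p0 <- match(tl[i], w$labels)
  if (w$sign[p0] == ts[i]) {
    L <- 1L
    while (i + L <= n && p0 + L <= n &&
           w$labels[p0 + L] == tl[i + L] && w$sign[p0 + L] == ts[i + L])
      L <- L + 1L
    list(kind = "a", src = p0, len = L, flipped = FALSE, dest = i)
  } else {
    L <- 1L
    while (i + L <= n && p0 - L >= 1L &&
           w$labels[p0 - L] == tl[i + L] && w$sign[p0 - L] == -ts[i + L])
      L <- L + 1L
    list(kind = "a", src = p0 - L + 1L, len = L, flipped = TRUE, dest = i)
  }
}

# Candidate (b): the longest run of w starting at position i that sits
# contiguously in the target; the block is moved (rightwards) to sit after
# its target left-neighbor. NULL when the neighbor's orientation in w
# disagrees with the target (no well-defined insertion point).
.candidate_working_run <- function(tl, ts, w, i) {
  n <- length(tl)
  q0 <- match(w$labels[i], tl)
  if (ts[q0] == w$sign[i]) {
    L <- 1L
    while (i + L <= n && q0 + L <= n &&
           tl[q0 + L] == w$labels[i + L] && ts[q0 + L] == w$sign[i + L])
      L <- L + 1L
    flipped <- FALSE
    nb <- q0 - 1L
  } else {
    L <- 1L
    while (i + L <= n && q0 - L >= 1L &&
           tl[q0 - L] == w$labels[i + L] && ts[q0 - L] == -w$sign[i + L])
      L <- L + 1L
    flipped <- TRUE
    nb <- q0 - L
  }
  if (nb < 1L) return(NULL)
  p_nb <- match(tl[nb], w$labels)
  if (is.na(p_nb) || p_nb < i + L) return(NULL)
  if (w$sign[p_nb] != ts[nb]) return(NULL)
  list(kind = "b", src = i, len = L, flipped = flipped, dest_after = p_nb)
}

.pick_candidate <- function(ca, cb, tl, ts, w) {
  if (is.null(cb)) return(ca)
  # a strand switch must be explained by moving the switched genes
  if (ca$flipped != cb$flipped) return(if (cb$flipped) cb else ca)
  if (cb$len < ca$len) {
    # accept (b) only if it strictly increases agreement with the target
    after <- .apply_move(w, cb)
    gain <- sum(after$labels == tl & after$sign == ts) -
      sum(w$labels == tl & w$sign == ts)
    if (gain > 0L) return(cb)
  }
  ca
}

.apply_move <- function(w, mv) {
  idx <- mv$src:(mv$src + mv$len - 1L)
  block <- list(labels = w$labels[idx], sign = w$sign[idx])
  if (mv$flipped) block <- .flip_signed(block$labels, block$sign)
  keep_l <- w$labels[-idx]
  keep_s <- w$sign[-idx]
  at <- if (identical(mv$kind, "a")) {
    mv$dest - 1L                      # insert so block starts at dest
  } else {
    match(w$labels[mv$dest_after], keep_l)  # insert right after neighbor
  }
  gene_order(append(keep_l, block$labels, after = at),
             append(keep_s, block$sign, after = at))
}

.type_event <- function(mv, w, categories) {
  idx <- mv$src:(mv$src + mv$len - 1L)
  genes <- w$labels[idx]
  traversed_idx <- if (identical(mv$kind, "a")) {
    if (mv$dest < mv$src) mv$dest:(mv$src - 1L) else integer()
  } else {
    if (mv$dest_after >= mv$src + mv$len) (mv$src + mv$len):mv$dest_after
    else integer()
  }
  traversed <- w$labels[traversed_idx]
  in_place <- length(traversed) == 0L
  type <- if (mv$flipped && in_place) {
    "inversion"
  } else if (mv$flipped) {
    "inverted_translocation"
  } else if (any(categories[traversed] %in% c("PCG", "rRNA"))) {
    "translocation"
  } else {
    "shuffling"
  }
  desc <- sprintf("%s of [%s]%s", type, paste(genes, collapse = " "),
                  if (in_place) " in place"
                  else sprintf(" across [%s]", paste(traversed,
                                                     collapse = " ")))
  list(type = type, genes = genes, flipped = mv$flipped,
       traversed = traversed, description = desc)
}
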