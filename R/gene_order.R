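#' Signed circular gene order
#'
#' A circular, signed permutation of gene labels: orientation `+` means
#' the gene lies on the H (forward) strand, `-` on the L strand. Two
#' orders are equivalent when one is a rotation of the other, or a full
#' reversal with all signs flipped (reading the circle from the other
#' strand); [canonicalize_gene_order()] maps each equivalence class to a
#' unique representative.
#'
#' @param labels Character vector of unique gene labels, in circular
#'   order.
#' @param sign Orientations: `+1`/`-1`, or characters `"+"`/`"-"`, or
#'   strand letters `"H"`/`"L"`.
#' @return An object of class `gene_order`.
#' @examples
#' gene_order(c("COX1", "trnD", "COX2"), c("+", "-", "+"))
#' @export
gene_order <- function(labels, sign = rep(1L, length(labels))) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  if (anyDuplicated(labels))
    stop("duplicate labels in gene order: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (is.character(sign))
    sign <- ifelse(sign %in% c("+", "H"), 1L,
                   ifelse(sign %in% c("-", "L"), -1L, NA_integer_))
  sign <- as.integer(sign)
  if (length(sign) != length(labels) || anyNA(sign) ||
      !all(sign %in% c(-1L, 1L)))
    stop("sign must be +/- (or H/L) for every label")
  structure(list(labels = labels, sign = sign), class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("gene_order (circular, %d genes):\n", length(x$labels)))
  cat(" ", paste0(x$labels, ifelse(x$sign > 0, "+", "-"), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$labels)

#' Read / write a gene-order file
#'
#' One line per gene: `label<TAB>+` or `label<TAB>-`; the circle is
#' implied.
#'
#' @param path File path.
#' @return [read_gene_order()]: a [gene_order()]. [write_gene_order()]:
#'   `path`, invisibly.
#' @examples
#' ref <- read_gene_order(mito_example("ancestral_gastropod_order.tsv"))
#' @export
read_gene_order <- function(path) {
  lines <- readLines(path)
  lines <- lines[!is_blank(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) stop("malformed gene-order line: '", lines[bad][1], "'")
  gene_order(vapply(parts, `[[`, character(1), 1L),
             vapply(parts, `[[`, character(1), 2L))
}

#' @rdname read_gene_order
#' @param order A [gene_order()].
#' @export
write_gene_order <- function(order, path) {
  writeLines(paste0(order$labels, "\t", ifelse(order$sign > 0, "+", "-")),
             path)
  invisible(path)
}

#' Gene order of an annotation
#'
#' Genes sorted by start position; orientation from strand (H = `+`).
#' The result is canonicalized so that the anchor gene (COX1 when
#' present) comes first with `+` orientation.
#'
#' @param annotation A nonempty [mito_annotation()].
#' @param anchor Anchor gene for canonicalization.
#' @return A [gene_order()].
#' @export
order_from_annotation <- function(annotation, anchor = "COX1") {
  g <- annotation$genes
  if (!nrow(g)) stop("empty annotation")
  canonicalize_gene_order(gene_order(g$name, g$strand), anchor = anchor)
}

.rotate_order <- function(x, i) {
  n <- length(x$labels)
  idx <- ((seq_len(n) + i - 2L) %% n) + 1L
  gene_order(x$labels[idx], x$sign[idx])
}

.reverse_flip <- function(x) {
  gene_order(rev(x$labels), -rev(x$sign))
}

#' Canonical representative of a circular signed order
#'
#' Rotates the circle so `anchor` (COX1 by default, else the
#' lexicographically smallest label) comes first; if the anchor is on the
#' `-` strand the whole circle is read from the other strand first
#' (reversal with sign flip), so the anchor is always `+`.
#'
#' @param order A [gene_order()].
#' @param anchor Anchor label.
#' @return A [gene_order()] in canonical form.
#' @export
canonicalize_gene_order <- function(order, anchor = "COX1") {
  if (!anchor %in% order$labels) anchor <- sort(order$labels)[1]
  i <- match(anchor, order$labels)
  if (order$sign[i] < 0) {
    order <- .reverse_flip(order)
    i <- match(anchor, order$labels)
  }
  .rotate_order(order, i)
}

#' Test equivalence of two circular signed orders
#'
#' @param a,b [gene_order()] objects over the same label set.
#' @param anchor Anchor label for canonicalization.
#' @return `TRUE` iff the orders are identical up to rotation and
#'   strand-of-reading.
#' @export
orders_equivalent <- function(a, b, anchor = "COX1") {
  ca <- canonicalize_gene_order(a, anchor)
  cb <- canonicalize_gene_order(b, anchor)
  identical(ca$labels, cb$labels) && identical(ca$sign, cb$sign)
}

.check_same_labels <- function(query, ref) {
  only_q <- setdiff(query$labels, ref$labels)
  only_r <- setdiff(ref$labels, query$labels)
  if (length(only_q) || length(only_r))
    stop("label sets differ; only in query: {",
         paste(only_q, collapse = ", "), "}, only in reference: {",
         paste(only_r, collapse = ", "), "}")
}

# Canonical key for a signed circular adjacency (a,b): reading the circle
# from the other strand turns (a,b) into (-b,-a), so both spellings map to
# one key.
.adjacency_keys <- function(order) {
  n <- length(order$labels)
  nxt <- c(seq_len(n)[-1], 1L)
  a <- paste0(ifelse(order$sign > 0, "+", "-"), order$labels)
  b <- paste0(ifelse(order$sign[nxt] > 0, "+", "-"), order$labels[nxt])
  flip <- function(x) ifelse(substr(x, 1, 1) == "+",
                             sub("^\\+", "-", x), sub("^-", "\\+", x))
  fwd <- paste(a, b, sep = "|")
  bwd <- paste(flip(b), flip(a), sep = "|")
  pmin(fwd, bwd)
}

#' Breakpoints between two circular signed gene orders
#'
#' A breakpoint is a signed adjacency of the query absent from the
#' reference (adjacencies are compared up to strand-of-reading, so a
#' fully reversed-and-flipped circle has zero breakpoints). The count is
#' symmetric in its arguments.
#'
#' @param query,ref [gene_order()] objects over identical label sets.
#' @return List with `count` and `shared` (the preserved adjacency keys).
#' @export
breakpoints <- function(query, ref) {
  .check_same_labels(query, ref)
  kq <- .adjacency_keys(query)
  kr <- .adjacency_keys(ref)
  shared <- intersect(kq, kr)
  list(count = length(kq) - length(shared), shared = shared)
}

#' Synteny blocks shared by two circular signed orders
#'
#' Maximal runs of genes contiguous and co-oriented in both orders; a run
#' that matches a reference segment in reversed order with flipped signs
#' counts as a single inverted block. The blocks partition the genes.
#'
#' @param query,ref [gene_order()] objects over identical label sets.
#' @return List of blocks, each a list with `labels` (in query order),
#'   `sign` (query orientation), and `direction` (`"forward"` or
#'   `"inverted"` relative to the reference; single genes are
#'   `"forward"` when signs agree).
#' @export
synteny_blocks <- function(query, ref) {
  .check_same_labels(query, ref)
  n <- length(query$labels)
  pos_r <- match(query$labels, ref$labels)
  sign_r <- ref$sign[pos_r]
  same <- query$sign == sign_r   # per-gene orientation agreement
  nxt <- c(seq_len(n)[-1], 1L)
  chained <- logical(n)          # chained[i]: i and i+1 stay in one block
  for (i in seq_len(n)) {
    j <- nxt[i]
    chained[i] <- if (same[i] && same[j]) {
      (pos_r[i] %% n) + 1L == pos_r[j]
    } else if (!same[i] && !same[j]) {
      (pos_r[j] %% n) + 1L == pos_r[i]
    } else FALSE
  }
  if (all(chained)) {
    return(list(list(labels = query$labels, sign = query$sign,
                     direction = if (all(same)) "forward" else "inverted")))
  }
  # block boundaries after each i with chained[i] == FALSE
  starts <- nxt[which(!chained)]
  starts <- sort(starts)
  blocks <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    e_excl <- if (k < length(starts)) starts[k + 1L] else starts[1L]
    idx <- s
    while ((idx[length(idx)] %% n) + 1L != e_excl)
      idx <- c(idx, (idx[length(idx)] %% n) + 1L)
    blocks[[k]] <- list(
      labels = query$labels[idx],
      sign = query$sign[idx],
      direction = if (all(same[idx])) "forward"
                  else if (all(!same[idx])) "inverted"
                  else "mixed"
    )
  }
  blocks
}
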