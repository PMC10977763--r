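test_that("canonicalization is invariant to rotation and reading strand", {
  ord <- gene_order(c("COX1", "trnA", "NAD2", "trnB"),
                    c("+", "-", "+", "+"))
  for (k in 1:3) {
    rot <- gene_order(c(ord$labels[-(1:k)], ord$labels[1:k]),
                      c(ord$sign[-(1:k)], ord$sign[1:k]))
    expect_true(orders_equivalent(ord, rot))
  }
  flipped <- gene_order(rev(ord$labels), -rev(ord$sign))
  expect_true(orders_equivalent(ord, flipped))
  expect_false(orders_equivalent(
    ord, gene_order(ord$labels, c("-", "-", "+", "+"))))
})

test_that("order_from_annotation starts at COX1+ regardless of origin", {
  ann <- table2_annotation()
  ord <- order_from_annotation(ann)
  expect_equal(length(ord), 37L)
  expect_equal(ord$labels[1:6],
               c("COX1", "COX2", "trnD", "ATP8", "ATP6", "trnM"))
  expect_equal(ord$sign[1:6], c(1L, 1L, 1L, 1L, 1L, -1L))
  # rotate the annotation's origin: same canonical order
  g <- ann$genes
  shift <- 5000L
  g$start <- ((g$start + shift - 1L) %% ann$genome_length) + 1L
  g$end <- ((g$end + shift - 1L) %% ann$genome_length) + 1L
  ann2 <- mito_annotation(g, ann$genome_length)
  ord2 <- order_from_annotation(ann2)
  expect_identical(ord$labels, ord2$labels)
  expect_identical(ord$sign, ord2$sign)
})

test_that("breakpoint counts match an adjacency-enumeration oracle", {
  # independent oracle: enumerate signed circular adjacencies by hand,
  # closing each under the reading-direction symmetry (a,b) ~ (-b,-a)
  adj_oracle <- function(labels, sign) {
    n <- length(labels)
    out <- character(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      f <- paste0(sign[i], labels[i], ">", sign[j], labels[j])
      b <- paste0(-sign[j], labels[j], ">", -sign[i], labels[i])
      out <- c(out, min(f, b))
    }
    out
  }
  bp_oracle <- function(q, r)
    length(setdiff(adj_oracle(q$labels, q$sign),
                   adj_oracle(r$labels, r$sign)))

  ref <- toy_order(10)
  expect_equal(breakpoints(ref, ref)$count, 0L)

  # 3-gene internal block reversed in place with signs flipped
  inv <- gene_order(c("A", "B", "E", "D", "C", "F", "G", "H", "I", "J"),
                    c(1, 1, -1, -1, -1, 1, 1, 1, 1, 1))
  expect_equal(breakpoints(inv, ref)$count, 2L)
  expect_equal(breakpoints(inv, ref)$count, bp_oracle(inv, ref))

  # single gene moved between two distant genes
  mv <- gene_order(c("A", "C", "D", "E", "F", "G", "B", "H", "I", "J"),
                   rep(1L, 10))
  expect_equal(breakpoints(mv, ref)$count, 3L)
  expect_equal(breakpoints(mv, ref)$count, bp_oracle(mv, ref))

  # symmetry
  expect_equal(breakpoints(mv, ref)$count, breakpoints(ref, mv)$count)
  expect_error(breakpoints(toy_order(9), ref), "label sets differ")
})

test_that("synteny blocks partition the genes and honor inversions", {
  ref <- toy_order(10)
  expect_length(synteny_blocks(ref, ref), 1L)
  flip_all <- gene_order(rev(ref$labels), -rev(ref$sign))
  blk <- synteny_blocks(flip_all, ref)
  expect_length(blk, 1L)
  expect_equal(blk[[1]]$direction, "inverted")

  inv <- gene_order(c("A", "B", "E", "D", "C", "F", "G", "H", "I", "J"),
                    c(1, 1, -1, -1, -1, 1, 1, 1, 1, 1))
  blocks <- synteny_blocks(inv, ref)
  # concatenating blocks in query order reproduces the query circle
  lab <- unlist(lapply(blocks, `[[`, "labels"))
  expect_setequal(lab, inv$labels)
  expect_equal(length(lab), length(unique(lab)))
  inv_blk <- Filter(function(b) b$direction == "inverted", blocks)
  expect_length(inv_blk, 1L)
  expect_equal(inv_blk[[1]]$labels, c("E", "D", "C"))
})

test_that("the ancestral comparison preserves the M-Y-C-W-Q-G-E cluster", {
  ann <- table2_annotation()
  blocks <- synteny_blocks(order_from_annotation(ann), ancestral_order())
  cluster <- c("trnM", "trnY", "trnC", "trnW", "trnQ", "trnG", "trnE")
  hit <- Filter(function(b) identical(b$labels, cluster), blocks)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$direction, "forward")
})

test_that("constructed single events are classified by type", {
  ref <- gene_order(c("COX1", "trnA", "trnB", "NAD1", "trnC", "NAD2",
                      "trnD", "rrnS"), rep(1L, 8))
  # in-place strand switch
  inv <- gene_order(ref$labels, c(1, 1, -1, 1, 1, 1, 1, 1))
  ev <- classify_events(inv, ref)$events
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "inversion")
  expect_equal(ev[[1]]$genes, "trnB")

  # tRNA hops over its tRNA neighbor: shuffling
  shf <- gene_order(c("COX1", "trnB", "trnA", "NAD1", "trnC", "NAD2",
                      "trnD", "rrnS"), rep(1L, 8))
  ev <- classify_events(shf, ref)$events
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "shuffling")

  # tRNA crosses two PCGs and a tRNA: translocation
  trl <- gene_order(c("COX1", "trnB", "NAD1", "trnC", "NAD2", "trnA",
                      "trnD", "rrnS"), rep(1L, 8))
  ev <- classify_events(trl, ref)$events
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "translocation")
  expect_equal(ev[[1]]$genes, "trnA")

  # moved and strand-switched: inverted translocation
  itr <- gene_order(c("COX1", "trnB", "NAD1", "trnC", "NAD2", "trnA",
                      "trnD", "rrnS"), c(1, 1, 1, 1, 1, -1, 1, 1))
  ev <- classify_events(itr, ref)$events
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "inverted_translocation")

  # no differences, no events
  rep0 <- classify_events(ref, ref)
  expect_equal(rep0$breakpoint_count, 0L)
  expect_length(rep0$events, 0L)
})

test_that("the published rearrangements are recovered against the ancestor", {
  rep <- classify_events(order_from_annotation(table2_annotation()),
                         ancestral_order())
  types <- vapply(rep$events, `[[`, character(1), "type")
  genes <- lapply(rep$events, `[[`, "genes")
  # the M-Y-C-W-Q-G-E cluster relocates (intact) downstream of ATP6
  cluster <- c("trnM", "trnY", "trnC", "trnW", "trnQ", "trnG", "trnE")
  i <- which(vapply(genes, function(g) identical(g, cluster), logical(1)))
  expect_length(i, 1L)
  expect_equal(types[i], "translocation")
  # the large span inverts and translocates; collectively the inverted
  # events carry the named PCGs and rRNAs
  inv_genes <- unlist(genes[types %in% c("inversion",
                                         "inverted_translocation")])
  expect_true(all(c("NAD5", "NAD4", "NAD4L", "CYTB", "NAD6", "NAD1",
                    "rrnL", "rrnS") %in% inv_genes))
  expect_true(rep$heuristic)
})
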