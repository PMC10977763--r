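# Constrained cloverleaf folding. The layout searched is the canonical
# tRNA cloverleaf read 5'->3':
#   acceptor 5' side (7 nt) | link1 | D arm (stem s_D, loop, stem) | link2 |
#   anticodon arm (stem s_A, loop 7) | variable region | T arm (stem s_T,
#   loop) | acceptor 3' side (7 nt) | discriminator (<= 2 nt)
# plus degenerate variants in which the D arm and/or the T arm is replaced
# by an unstructured span (the D-armless Ser and T-armless Ala tRNAs of
# many invertebrate mitogenomes). All admissible layouts are enumerated
# and scored; the best is returned.

#' Default cloverleaf search parameters
#'
#' Stem/loop ranges and scoring used by [fold_cloverleaf()]. Scoring is +2
#' per Watson-Crick pair, +1 per G·U wobble, -2 per mismatch; an arm is
#' called present only when its best stem holds at least
#' `min_arm_pairs` paired (WC or wobble) positions and has positive score.
#'
#' @return Named list of parameters.
#' @export
cloverleaf_params <- function() {
  list(
    acceptor_stem = 7L,
    d_stem = 3:4, d_loop = 4:12,
    ac_stem = 4:5, ac_loop = 7L,
    var_loop = 3:23,
    t_stem = 4:5, t_loop = 3:9,
    link1 = 0:3, link2 = 0:2,
    discriminator = 0:2,
    d_absent_span = 4:15,     # unstructured span replacing a missing D arm
    t_absent_span = 0:12,     # unstructured span replacing a missing T arm
    score_wc = 2L, score_wobble = 1L, score_mismatch = -2L,
    min_arm_pairs = 3L
  )
}

.pair_class <- function(x, y) {
  # x, y: single uppercase DNA characters (T for U)
  wc <- (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
  if (wc) return("WC")
  if ((x == "G" && y == "T") || (x == "T" && y == "G")) return("wobble")
  "mismatch"
}

# Score a stem pairing positions p5[k] with p3[k] (already matched up).
.stem_score <- function(chars, p5, p3, par) {
  classes <- vapply(seq_along(p5), function(k)
    .pair_class(chars[p5[k]], chars[p3[k]]), character(1))
  score <- sum((classes == "WC") * par$score_wc +
                 (classes == "wobble") * par$score_wobble +
                 (classes == "mismatch") * par$score_mismatch)
  list(score = score, classes = classes,
       paired = sum(classes != "mismatch"),
       pairs = data.frame(pos5 = p5, pos3 = p3, class = classes,
                          stringsAsFactors = FALSE))
}

#' Fold a tRNA sequence into a constrained cloverleaf
#'
#' Exhaustively searches the constrained cloverleaf layout space (see
#' [cloverleaf_params()]) and returns the highest-scoring fold. Arm
#' presence for the D and T arms follows the degenerate-tRNA semantics:
#' an arm is absent when no acceptable stem exists under the search
#' constraints. Ties are broken by total score, then total paired count,
#' then fewest mismatches, then shortest variable loop; identical input
#' always yields an identical layout.
#'
#' @param seq tRNA sequence, DNA or RNA alphabet, typically 45-90 nt.
#' @param expected_anticodon Optional 3-mer; layouts placing it centrally
#'   in the anticodon loop are preferred ahead of score.
#' @param params Search parameters from [cloverleaf_params()].
#' @return A `cloverleaf_fold`: list with per-arm stems (`acceptor`, `D`,
#'   `anticodon`, `T`: each `NULL` or a list with `pairs`, `score`,
#'   `loop`), `arm_present` flags, `anticodon` triplet, `var_loop` span,
#'   `score`, and `failed` flag. Sequences with no feasible layout return
#'   a fold-failure result (arms absent), not an error.
#' @examples
#' tr <- generate_trna(anticodon = "TGC", seed = 1)
#' fold <- fold_cloverleaf(tr$seq)
#' fold$arm_present
#' @export
fold_cloverleaf <- function(seq, expected_anticodon = NULL,
                            params = cloverleaf_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  rna_in <- grepl("U", toupper(seq))
  s <- toupper(chartr("Uu", "Tt", seq))
  if (grepl("[^ACGT]", s)) stop("invalid characters in tRNA sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  par <- params
  if (!is.null(expected_anticodon))
    expected_anticodon <- toupper(chartr("U", "T", expected_anticodon))

  # -- vectorized layout search -------------------------------------------
  # Per-stem (score, paired, mismatch) statistics are precomputed for every
  # admissible stem placement; the combinatorial enumeration over layouts
  # then only sums table entries.
  ci <- match(chars, c("A", "C", "G", "T"))
  SM <- matrix(par$score_mismatch, 4, 4)
  PM <- matrix(0L, 4, 4)
  wc <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))
  SM[wc] <- par$score_wc; PM[wc] <- 1L
  gu <- rbind(c(3, 4), c(4, 3))
  SM[gu] <- par$score_wobble; PM[gu] <- 1L
  stem_stat <- function(p5_start, s, p3_last) {
    k <- 0:(s - 1L)
    idx <- cbind(ci[p5_start + k], ci[p3_last - k])
    c(score = sum(SM[idx]), paired = sum(PM[idx]))
  }
  inner_start <- par$acceptor_stem + 1L

  # acceptor stem per discriminator choice
  acc_tab <- lapply(par$discriminator, function(disc) {
    if (L - disc - par$acceptor_stem <= par$acceptor_stem) return(NULL)
    stem_stat(1L, par$acceptor_stem, L - disc)
  })

  # D-arm variants (present: link1 x stem x loop; absent: plain span)
  d_var <- do.call(rbind, c(
    lapply(par$link1, function(l1)
      expand.grid(present = TRUE, l1 = l1, sD = par$d_stem,
                  lD = par$d_loop)),
    list(data.frame(present = FALSE, l1 = 0L,
                    sD = 0L, lD = par$d_absent_span))))
  d_var$len <- ifelse(d_var$present, d_var$l1 + 2L * d_var$sD + d_var$lD,
                      d_var$lD)
  d_var$score <- 0; d_var$paired <- 0L
  for (r in which(d_var$present)) {
    d5s <- inner_start + d_var$l1[r]
    if (d5s + 2L * d_var$sD[r] + d_var$lD[r] - 1L > L) {
      d_var$score[r] <- -Inf
      next
    }
    st <- stem_stat(d5s, d_var$sD[r],
                    d5s + 2L * d_var$sD[r] + d_var$lD[r] - 1L)
    d_var$score[r] <- st[["score"]]; d_var$paired[r] <- st[["paired"]]
  }

  # anticodon stem for every feasible start position
  sA_vals <- par$ac_stem
  ac_tab <- array(NA_real_, c(L, length(sA_vals), 2L))
  for (a in seq_along(sA_vals)) {
    sA <- sA_vals[a]
    span <- 2L * sA + par$ac_loop
    if (L - span < inner_start) next
    for (p in inner_start:(L - span)) {
      st <- stem_stat(p, sA, p + span - 1L)
      ac_tab[p, a, 1L] <- st[["score"]]; ac_tab[p, a, 2L] <- st[["paired"]]
    }
  }

  # T-arm variants per discriminator (anchored at the acceptor 3' side)
  t_var <- rbind(expand.grid(present = TRUE, sT = par$t_stem,
                             lT = par$t_loop),
                 data.frame(present = FALSE, sT = 0L, lT = 0L))
  t_var$len <- ifelse(t_var$present, 2L * t_var$sT + t_var$lT, 0L)
  t_stat <- function(disc, r) {
    t_end <- L - disc - par$acceptor_stem
    t_start <- t_end - t_var$len[r] + 1L
    if (t_start <= inner_start) return(c(score = -Inf, paired = 0))
    stem_stat(t_start, t_var$sT[r], t_end)
  }

  combos <- expand.grid(di = seq_along(par$discriminator),
                        dv = seq_len(nrow(d_var)),
                        l2 = par$link2,
                        ai = seq_along(sA_vals),
                        tv = seq_len(nrow(t_var)))
  disc_v <- par$discriminator[combos$di]
  keep <- !vapply(acc_tab[combos$di], is.null, logical(1))
  combos <- combos[keep, , drop = FALSE]; disc_v <- disc_v[keep]
  ac_start <- inner_start + d_var$len[combos$dv] + combos$l2
  sA_v <- sA_vals[combos$ai]
  inner_end <- L - disc_v - par$acceptor_stem
  v <- inner_end - ac_start + 1L - (2L * sA_v + par$ac_loop) -
    t_var$len[combos$tv]
  v_max <- ifelse(t_var$present[combos$tv], max(par$var_loop),
                  max(par$var_loop) + max(par$t_absent_span))
  ok <- v >= min(par$var_loop) & v <= v_max & ac_start >= inner_start &
    (ac_start + 2L * sA_v + par$ac_loop - 1L) <= inner_end
  combos <- combos[ok, , drop = FALSE]
  if (nrow(combos)) {
    disc_v <- disc_v[ok]; ac_start <- ac_start[ok]; sA_v <- sA_v[ok]
    v <- v[ok]
    acc_sc <- vapply(acc_tab[combos$di], `[[`, numeric(1), "score")
    acc_pr <- vapply(acc_tab[combos$di], `[[`, numeric(1), "paired")
    ac_sc <- ac_tab[cbind(ac_start, combos$ai, 1L)]
    ac_pr <- ac_tab[cbind(ac_start, combos$ai, 2L)]
    t_lut <- array(0, c(length(par$discriminator), nrow(t_var), 2L))
    for (di in seq_along(par$discriminator))
      for (r2 in seq_len(nrow(t_var)))
        t_lut[di, r2, ] <- t_stat(par$discriminator[di], r2)
    t_st <- cbind(t_lut[cbind(combos$di, combos$tv, 1L)],
                  t_lut[cbind(combos$di, combos$tv, 2L)])
    total <- acc_sc + d_var$score[combos$dv] + ac_sc + t_st[, 1L]
    paired <- acc_pr + d_var$paired[combos$dv] + ac_pr + t_st[, 2L]
    n_pairs <- par$acceptor_stem +
      ifelse(d_var$present[combos$dv], d_var$sD[combos$dv], 0L) + sA_v +
      ifelse(t_var$present[combos$tv], t_var$sT[combos$tv], 0L)
    mism <- n_pairs - paired
    anticodons <- substring(s, ac_start + sA_v + 2L, ac_start + sA_v + 4L)
    ac_ok <- if (is.null(expected_anticodon)) rep(0L, nrow(combos))
             else as.integer(anticodons == expected_anticodon)
    pick <- order(-ac_ok, -total, -paired, mism, v)[1L]
    r <- combos[pick, ]
    dv <- as.list(d_var[r$dv, ])
    tv <- as.list(t_var[r$tv, ])
    acc_full <- .stem_score(chars, seq_len(par$acceptor_stem),
                            (L - disc_v[pick]):(L - disc_v[pick] -
                                                  par$acceptor_stem + 1L),
                            par)
    best <- .score_layout(chars, par, disc_v[pick], acc_full, dv, r$l2,
                          sA_vals[r$ai], tv, v[pick], ac_start[pick],
                          L - disc_v[pick] - par$acceptor_stem,
                          expected_anticodon)
  } else best <- NULL

  if (is.null(best)) {
    return(structure(
      list(acceptor = NULL, D = NULL, anticodon_arm = NULL, T = NULL,
           arm_present = c(acceptor = FALSE, D = FALSE, anticodon = FALSE,
                           T = FALSE),
           anticodon = NA_character_, var_loop = NA_integer_,
           score = -Inf, failed = TRUE, length = L),
      class = "cloverleaf_fold"))
  }
  out <- best$fold
  out$length <- L
  if (rna_in && !is.na(out$anticodon))
    out$anticodon <- chartr("T", "U", out$anticodon)
  class(out) <- "cloverleaf_fold"
  out
}

.score_layout <- function(chars, par, disc, acc, dv, l2, sA, tv, v,
                          ac_start, inner_end, expected_anticodon) {
  d_arm <- NULL
  d_score <- 0L
  if (dv$present) {
    d5 <- (ac_start - l2 - dv$len + dv$l1):(ac_start - l2 - dv$len +
                                              dv$l1 + dv$sD - 1L)
    d3_first <- d5[dv$sD] + dv$lD + dv$sD
    d3 <- d3_first:(d3_first - dv$sD + 1L)
    st <- .stem_score(chars, d5, d3, par)
    d_arm <- c(st, list(loop = c(d5[dv$sD] + 1L, d3_first - dv$sD)))
    d_score <- st$score
  }
  ac5 <- ac_start:(ac_start + sA - 1L)
  ac3 <- (ac_start + 2L * sA + par$ac_loop - 1L):(ac_start + sA +
                                                    par$ac_loop)
  ac_st <- .stem_score(chars, ac5, ac3, par)
  loop_start <- ac5[sA] + 1L
  anticodon <- paste(chars[(loop_start + 2L):(loop_start + 4L)],
                     collapse = "")
  t_arm <- NULL
  t_score <- 0L
  if (tv$present) {
    t_start <- ac_start + 2L * sA + par$ac_loop + v
    t5 <- t_start:(t_start + tv$sT - 1L)
    t3 <- (t_start + 2L * tv$sT + tv$lT - 1L):(t_start + tv$sT + tv$lT)
    st <- .stem_score(chars, t5, t3, par)
    t_arm <- c(st, list(loop = c(t5[tv$sT] + 1L, t3[1L] - tv$sT)))
    t_score <- st$score
  }
  total <- acc$score + d_score + ac_st$score + t_score
  total_paired <- acc$paired + ac_st$paired +
    (if (dv$present) d_arm$paired else 0L) +
    (if (tv$present) t_arm$paired else 0L)
  n_mismatch <- sum(acc$classes == "mismatch") +
    sum(ac_st$classes == "mismatch") +
    (if (dv$present) sum(d_arm$classes == "mismatch") else 0L) +
    (if (tv$present) sum(t_arm$classes == "mismatch") else 0L)
  ac_ok <- !is.null(expected_anticodon) && anticodon == expected_anticodon
  acceptable <- function(st)
    !is.null(st) && st$paired >= par$min_arm_pairs && st$score > 0L
  arm_present <- c(
    acceptor = acceptable(acc),
    D = dv$present && acceptable(d_arm),
    anticodon = acceptable(ac_st),
    T = tv$present && acceptable(t_arm)
  )
  # arm-absent semantics: no pairs reported for an absent arm
  if (!arm_present[["D"]]) d_arm <- NULL
  if (!arm_present[["T"]]) t_arm <- NULL
  fold <- list(
    acceptor = acc, D = d_arm, anticodon_arm = ac_st, T = t_arm,
    arm_present = arm_present,
    anticodon = anticodon,
    anticodon_loop = c(loop_start, loop_start + par$ac_loop - 1L),
    var_loop = v,
    discriminator = disc,
    score = total, failed = FALSE
  )
  list(fold = fold,
       rank_key = c(as.integer(ac_ok), total, total_paired,
                    -n_mismatch, -v))
}

#' Mismatched and wobble pairs of a cloverleaf fold
#'
#' @param fold A `cloverleaf_fold` from [fold_cloverleaf()].
#' @return List with `mismatches` and `wobbles`, data.frames of paired
#'   positions (`pos5`, `pos3`, `arm`).
#' @export
mismatch_report <- function(fold) {
  stopifnot(inherits(fold, "cloverleaf_fold"))
  arms <- list(acceptor = fold$acceptor, D = fold$D,
               anticodon = fold$anticodon_arm, T = fold$T)
  collect <- function(class) {
    out <- lapply(names(arms), function(a) {
      st <- arms[[a]]
      if (is.null(st)) return(NULL)
      p <- st$pairs[st$pairs$class == class, c("pos5", "pos3"),
                    drop = FALSE]
      if (!nrow(p)) return(NULL)
      p$arm <- a
      p
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(pos5 = integer(), pos3 = integer(),
                        arm = character(), stringsAsFactors = FALSE)
    out
  }
  list(mismatches = collect("mismatch"), wobbles = collect("wobble"))
}

#' Dot-bracket rendering of a cloverleaf fold
#'
#' @param fold A `cloverleaf_fold`.
#' @return Dot-bracket string of the fold's length.
#' @export
dot_bracket <- function(fold) {
  stopifnot(inherits(fold, "cloverleaf_fold"))
  db <- rep(".", fold$length)
  for (st in list(fold$acceptor, fold$D, fold$anticodon_arm, fold$T)) {
    if (is.null(st)) next
    ok <- st$pairs$class != "mismatch"
    db[st$pairs$pos5[ok]] <- "("
    db[st$pairs$pos3[ok]] <- ")"
  }
  paste(db, collapse = "")
}

#' @export
print.cloverleaf_fold <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("cloverleaf_fold: no feasible layout (fold failure)\n")
    return(invisible(x))
  }
  p <- x$arm_present
  cat(sprintf(
    "cloverleaf_fold: score %d | arms: acceptor %s, D %s, anticodon %s, T %s | anticodon %s\n",
    x$score, ifelse(p[["acceptor"]], "+", "-"),
    ifelse(p[["D"]], "+", "-"), ifelse(p[["anticodon"]], "+", "-"),
    ifelse(p[["T"]], "+", "-"), x$anticodon))
  invisible(x)
}

#' Check an anticodon against an amino acid under a genetic code
#'
#' True when the reverse complement of the anticodon, read as a codon,
#' translates to the amino acid — allowing standard third-position wobble
#' (anticodon first base U pairs codon-third A or G; anticodon first base
#' G pairs codon-third C or U).
#'
#' @param anticodon 3-letter DNA/RNA anticodon (5'->3').
#' @param amino_acid One- or three-letter amino-acid code.
#' @param code A [genetic_code()].
#' @return Logical, with attribute `"codons"`: the decoded codons (RNA)
#'   that translate to `amino_acid`.
#' @examples
#' validate_anticodon("GTC", "Asp")  # decodes GAC
#' @export
validate_anticodon <- function(anticodon, amino_acid,
                               code = genetic_code(5)) {
  stopifnot(is.character(anticodon), nchar(anticodon) == 3L)
  ac <- toupper(chartr("U", "T", anticodon))
  if (grepl("[^ACGT]", ac)) stop("invalid anticodon: ", anticodon)
  aa <- if (nchar(amino_acid) == 3L) {
    aa3 <- paste0(toupper(substr(amino_acid, 1, 1)),
                  tolower(substr(amino_acid, 2, 3)))
    if (!aa3 %in% names(.aa3to1)) stop("unknown amino acid: ", amino_acid)
    unname(.aa3to1[[aa3]])
  } else {
    toupper(amino_acid)
  }
  if (!aa %in% code$codon_to_aa) stop("unknown amino acid: ", amino_acid)
  base_codon <- revcomp(ac)
  third <- substr(base_codon, 3, 3)
  wobble_third <- switch(substr(ac, 1, 1),
                         T = c("A", "G"), G = c("C", "T"), third)
  codons <- unique(vapply(wobble_third, function(b) {
    paste0(substr(base_codon, 1, 2), b)
  }, character(1)))
  codons_rna <- chartr("T", "U", codons)
  hits <- codons_rna[code$codon_to_aa[codons_rna] == aa]
  out <- length(hits) > 0L
  attr(out, "codons") <- hits
  out
}

#' Fold every tRNA of an annotation
#'
#' @param annotation A [mito_annotation()] with sequence.
#' @param params Search parameters.
#' @return Named list of `cloverleaf_fold` objects, one per tRNA gene
#'   (L-strand genes folded on their sense strand).
#' @export
fold_all_trnas <- function(annotation, params = cloverleaf_params()) {
  if (is.null(annotation$sequence)) stop("annotation carries no sequence")
  g <- annotation$genes
  idx <- which(g$category == "tRNA")
  folds <- lapply(idx, function(i) {
    s <- circular_slice(annotation$sequence, g$start[i], g$end[i])
    if (g$strand[i] == "L") s <- revcomp(s)
    fold_cloverleaf(s, expected_anticodon = if (!is.na(g$anticodon[i]))
      g$anticodon[i] else NULL, params = params)
  })
  stats::setNames(folds, g$name[idx])
}
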