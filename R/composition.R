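#' AT-skew and GC-skew
#'
#' Compositional asymmetry statistics: `at_skew = (A - T) / (A + T)` and
#' `gc_skew = (G - C) / (G + C)`. Both are scale-invariant, so counts and
#' percentages give identical values. A zero denominator yields `NA` with
#' a warning (undefined skew), never an error.
#'
#' @param a,t,g,c Non-negative counts or percentages.
#' @return Skew value in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' at_skew(27.73, 42.47)   # -0.210 at 3 d.p.
#' gc_skew(18.08, 11.71)   #  0.214 at 3 d.p.
#' @export
at_skew <- function(a, t) {
  stopifnot(a >= 0, t >= 0)
  if (a + t == 0) {
    warning("undefined AT-skew: A + T == 0")
    return(NA_real_)
  }
  (a - t) / (a + t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  stopifnot(g >= 0, c >= 0)
  if (g + c == 0) {
    warning("undefined GC-skew: G + C == 0")
    return(NA_real_)
  }
  (g - c) / (g + c)
}

#' Base composition profile of a sequence
#'
#' Counts A/C/G/T (T and U treated alike), derives percentages, A+T
#' content, and both skews. IUPAC ambiguity codes are excluded from the
#' four counts and reported separately.
#'
#' @param sequence DNA (or RNA) string.
#' @param region_name Label carried into the profile.
#' @return A `composition_profile`: list with `region`, `size`, `counts`,
#'   `percent`, `at_content`, `at_skew`, `gc_skew`, `n_ambiguous`.
#' @examples
#' composition_profile("AATT")
#' @export
composition_profile <- function(sequence, region_name = "region") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "t", tolower(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- c(A = sum(chars == "a"), T = sum(chars == "t"),
              G = sum(chars == "g"), C = sum(chars == "c"))
  n_acgt <- sum(counts)
  n_amb <- length(chars) - n_acgt
  pct <- if (n_acgt > 0) 100 * counts / n_acgt else counts * NA_real_
  structure(
    list(region = region_name,
         size = length(chars),
         counts = as.list(counts),
         percent = as.list(pct),
         at_content = unname(pct[["A"]] + pct[["T"]]),
         at_skew = if (counts[["A"]] + counts[["T"]] > 0)
           at_skew(counts[["A"]], counts[["T"]]) else NA_real_,
         gc_skew = if (counts[["G"]] + counts[["C"]] > 0)
           gc_skew(counts[["G"]], counts[["C"]]) else NA_real_,
         n_ambiguous = n_amb),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "%s: %d nt | A %.2f%% T %.2f%% G %.2f%% C %.2f%% | A+T %.2f%% | AT-skew %.3f GC-skew %.3f\n",
    x$region, x$size, x$percent$A, x$percent$T, x$percent$G, x$percent$C,
    x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition of a gene, category, or the whole genome
#'
#' Pools the sense-strand nucleotides of all genes matching `region`
#' (L-strand genes are reverse-complemented before counting; genes
#' spanning the origin are stitched, never truncated). `region` may be a
#' gene name, a category (`"PCG"`, `"tRNA"`, `"rRNA"`), or `"genome"`,
#' which uses the full forward (H) strand — the convention under which
#' whole-genome skews are conventionally reported.
#'
#' @param annotation A [mito_annotation()] carrying a sequence.
#' @param region Region specifier.
#' @return A [composition_profile()].
#' @export
region_composition <- function(annotation, region = "genome") {
  if (is.null(annotation$sequence))
    stop("annotation carries no sequence")
  if (identical(region, "genome"))
    return(composition_profile(annotation$sequence, "genome"))
  g <- annotation$genes
  sel <- if (region %in% c("PCG", "tRNA", "rRNA")) {
    g$category == region
  } else {
    g$name == region
  }
  if (!any(sel)) stop("unknown region: '", region, "'")
  pieces <- vapply(which(sel), function(i) {
    s <- circular_slice(annotation$sequence, g$start[i], g$end[i])
    if (g$strand[i] == "L") revcomp(s) else s
  }, character(1))
  composition_profile(paste(pieces, collapse = ""), region)
}

#' Write composition profiles as a TSV table
#'
#' One row per profile, replicating the conventional region/size/
#' percentages/A+T/skew column layout (percentages at 2 d.p., skews at
#' 3 d.p.).
#'
#' @param profiles A list of [composition_profile()] objects.
#' @param path Output file path, or `NULL` to return the text.
#' @return TSV text, invisibly when written.
#' @export
write_composition_tsv <- function(profiles, path = NULL) {
  rows <- vapply(profiles, function(p) {
    paste(p$region, p$size,
          sprintf("%.2f", p$percent$A), sprintf("%.2f", p$percent$T),
          sprintf("%.2f", p$percent$G), sprintf("%.2f", p$percent$C),
          sprintf("%.2f", p$at_content),
          sprintf("%.3f", p$at_skew), sprintf("%.3f", p$gc_skew),
          sep = "\t")
  }, character(1))
  txt <- c("region\tsize\tA\tT\tG\tC\tat_content\tat_skew\tgc_skew", rows)
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
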