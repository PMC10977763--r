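#' Canonical mitochondrial gene vocabulary
#'
#' The 37 canonical metazoan mitochondrial gene labels used throughout the
#' package: 13 protein-coding genes (PCGs), 22 tRNAs (with the two leucine
#' and two serine isoacceptors distinguished as trnL1/trnL2 and
#' trnS1/trnS2), and the two rRNAs (rrnL = large subunit / 16S,
#' rrnS = small subunit / 12S).
#'
#' @return Character vector of 37 labels.
#' @export
mito_gene_vocabulary <- function() {
  c(
    "COX1", "COX2", "COX3", "ATP6", "ATP8",
    "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6", "CYTB",
    "rrnL", "rrnS",
    "trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
    "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
    "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY"
  )
}

# Amino-acid one-letter codes for tRNA labels, three-letter -> one-letter.
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

# Synonym table: uppercased, stripped raw label -> canonical. Covers the
# mixtures seen in annotation practice (COI/COX1, ND5/NAD5, Cytb/COB,
# 12S/srRNA/rrnS...).
.gene_synonyms <- local({
  syn <- c(
    COI = "COX1", CO1 = "COX1", COXI = "COX1", COX1 = "COX1",
    COII = "COX2", CO2 = "COX2", COXII = "COX2", COX2 = "COX2",
    COIII = "COX3", CO3 = "COX3", COXIII = "COX3", COX3 = "COX3",
    ATP6 = "ATP6", ATPASE6 = "ATP6", ATP8 = "ATP8", ATPASE8 = "ATP8",
    ND1 = "NAD1", NAD1 = "NAD1", ND2 = "NAD2", NAD2 = "NAD2",
    ND3 = "NAD3", NAD3 = "NAD3", ND4 = "NAD4", NAD4 = "NAD4",
    ND4L = "NAD4L", NAD4L = "NAD4L", ND5 = "NAD5", NAD5 = "NAD5",
    ND6 = "NAD6", NAD6 = "NAD6",
    CYTB = "CYTB", CYB = "CYTB", COB = "CYTB", CYTOCHROMEB = "CYTB",
    `16S` = "rrnL", `16SRRNA` = "rrnL", RRNL = "rrnL", LRRNA = "rrnL",
    `RRN16` = "rrnL",
    `12S` = "rrnS", `12SRRNA` = "rrnS", RRNS = "rrnS", SRRNA = "rrnS",
    `RRN12` = "rrnS"
  )
  # tRNA forms: trnX, tRNA-Xxx, tRNA-Xxx1/2, trnL1, trnS2, tRNA^Asp^ ...
  syn
})

#' Normalize a raw gene label to the canonical vocabulary
#'
#' Maps the synonyms found in annotation tables and GenBank files
#' (COI/COX1, ND5/NAD5, NAD4l/ND4L, Cytb/COB, 12S rRNA/rrnS,
#' tRNA-Asp/trnD, tRNA-Ser2/trnS2, ...) onto the 37-label vocabulary of
#' [mito_gene_vocabulary()]. Unknown labels pass through unchanged and are
#' flagged, never rejected.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector of normalized labels, with attribute
#'   `"unknown"` a logical vector marking labels that did not resolve.
#' @examples
#' normalize_gene_name(c("NAD4l", "COI", "tRNA-Ser2", "12S rRNA"))
#' @export
normalize_gene_name <- function(raw) {
  stopifnot(is.character(raw))
  out <- character(length(raw))
  unknown <- logical(length(raw))
  for (i in seq_along(raw)) {
    out[i] <- .normalize_one(raw[i])
    unknown[i] <- is.na(out[i])
    if (unknown[i]) out[i] <- raw[i]
  }
  attr(out, "unknown") <- unknown
  out
}

.normalize_one <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_character_)
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  # Direct / synonym match for PCGs and rRNAs.
  if (key %in% names(.gene_synonyms)) return(unname(.gene_synonyms[[key]]))
  vocab <- mito_gene_vocabulary()
  hit <- match(key, toupper(gsub("[^A-Za-z0-9]", "", vocab)))
  if (!is.na(hit)) return(vocab[hit])
  # tRNA forms: TRN<one-letter>[12] or TRNA<three-letter>[12].
  m <- regmatches(key, regexec("^TRNA?([A-Z]+?)([12]?)$", key))[[1]]
  if (length(m) == 3L) {
    aa <- m[2]; iso <- m[3]
    one <- if (nchar(aa) == 1L && aa %in% .aa3to1) {
      aa
    } else {
      aa3 <- paste0(substr(aa, 1, 1), tolower(substr(aa, 2, nchar(aa))))
      if (aa3 %in% names(.aa3to1)) unname(.aa3to1[[aa3]]) else NA_character_
    }
    if (!is.na(one)) {
      cand <- paste0("trn", one, iso)
      if (cand %in% vocab) return(cand)
      # Leu/Ser without isoacceptor number cannot resolve uniquely.
      if (one %in% c("L", "S") && !nzchar(iso)) return(NA_character_)
    }
  }
  NA_character_
}

# Gene category from a canonical (or raw) label.
gene_category <- function(name) {
  vapply(name, function(x) {
    if (grepl("^trn", x, ignore.case = TRUE) || grepl("^tRNA", x)) "tRNA"
    else if (grepl("^rrn", x, ignore.case = TRUE) || grepl("rRNA", x)) "rRNA"
    else "PCG"
  }, character(1), USE.NAMES = FALSE)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or vector of file names).
#' @examples
#' mito_example()
#' mito_example("desmaulus_table2.tsv")
#' @export
mito_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mitochar"))
  } else {
    path <- system.file("extdata", file, package = "mitochar")
    if (!nzchar(path)) stop("no packaged file named '", file, "'")
    path
  }
}
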