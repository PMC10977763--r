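# Internal helpers shared across modules.

# Reverse complement of a plain character DNA string (IUPAC-aware via
# Biostrings). Kept as character in/out; annotations store sequences as
# plain strings.
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Extract positions start..end from a circular sequence, 1-based inclusive,
# wrapping through the origin when end < start. Never truncates.
circular_slice <- function(sequence, start, end) {
  n <- nchar(sequence)
  stopifnot(start >= 1L, start <= n, end >= 1L, end <= n)
  if (end >= start) {
    substr(sequence, start, end)
  } else {
    paste0(substr(sequence, start, n), substr(sequence, 1L, end))
  }
}

# Length of a 1-based inclusive circular span.
circular_span_length <- function(start, end, genome_length) {
  if (end >= start) end - start + 1L else (genome_length - start + 1L) + end
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) is.na(x) | !nzchar(trimws(x))
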