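# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# 61 sense codons.
NONSTOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                  DNA_BASES, paste0)),
  c("TAA", "TAG", "TGA"))

#' Truncate to one decimal place
#'
#' Reporting convention used throughout: shares and means are printed to one
#' decimal by truncation (52.777... is reported as 52.7). Raw values are kept
#' alongside wherever a truncated figure is emitted.
#'
#' @param x numeric vector.
#' @return `x` truncated to one decimal.
#' @keywords internal
trunc1 <- function(x) trunc(x * 10 + 1e-9) / 10

#' @keywords internal
pct1 <- function(n, denom) trunc1(100 * n / denom)

# Split a nucleotide string into a character vector of single bases.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Assert a string is non-empty and over the DNA alphabet; reports the first
# offending position in the error.
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty nucleotide string", call. = FALSE)
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0L)
    stop(what, " contains non-ACGT character at position ", bad, call. = FALSE)
  invisible(x)
}

# Translate an in-frame nucleotide string via the standard genetic code;
# returns "" for "". Table-based: cheap enough to call per transcript.
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return("")
  if (n %% 3L != 0L)
    stop("cannot translate: length ", n, " is not a multiple of 3",
         call. = FALSE)
  codons <- substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    stop("cannot translate: non-ACGT codon", call. = FALSE)
  paste(aa, collapse = "")
}

# Longest common suffix length of two strings, compared bytewise.
common_suffix_len <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  n <- min(length(ia), length(ib))
  if (n == 0L) return(0L)
  ra <- ia[length(ia) - seq_len(n) + 1L]
  rb <- ib[length(ib) - seq_len(n) + 1L]
  mism <- which(ra != rb)
  if (length(mism) == 0L) n else mism[1L] - 1L
}

# Longest common prefix length of two strings.
common_prefix_len <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  n <- min(length(ia), length(ib))
  if (n == 0L) return(0L)
  mism <- which(ia[seq_len(n)] != ib[seq_len(n)])
  if (length(mism) == 0L) n else mism[1L] - 1L
}

# Random DNA string of length n (uses the current RNG stream).
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Truncated geometric draw on 0..max with success probability p:
# P(t) proportional to (1 - p)^t.
rtgeom <- function(n, p, max) {
  if (max <= 0L) return(rep.int(0L, n))
  t <- 0:max
  w <- (1 - p)^t
  sample(t, n, replace = TRUE, prob = w / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
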