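# Constant-region marker vectors and their explanations.
#
# Observed constant portions are reduced to their bases at the locus'
# variable marker positions. Per isotype at most two germline alleles are
# expected; observed vectors in excess of the allele pair are explained, in
# order of parsimony, as exon-swap products (alternative splicing that
# combines the exon-1 block of one allele with the exon-3 block of another)
# or as single-crossover recombinational-diversification hybrids (possibly
# across isotypes); anything needing two or more switches is reported novel.

#' Collect marker vectors from annotated clones
#'
#' Groups clones by their (isotype, marker vector) pair and counts them.
#' Marker positions beyond the sequenced region are recorded as `N`.
#'
#' @param records annotation table with columns `c_call` and
#'   `c_marker_vector` (as produced by [annotate_transcripts()]), optionally
#'   `tissue`.
#' @param by optional extra grouping columns present in `records`
#'   (e.g. `"tissue"`).
#' @return data.frame with the grouping columns, `c_call`, `vector` and
#'   `count`; counts sum to the number of records with a called C.
#' @export
collect_marker_vectors <- function(records, by = character()) {
  ok <- !is.na(records$c_call) & !is.na(records$c_marker_vector)
  r <- records[ok, , drop = FALSE]
  key <- do.call(paste, c(lapply(by, function(b) r[[b]]),
                          list(r$c_call, r$c_marker_vector, sep = "\r")))
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- c(by, "c_call", "vector")
  out$count <- as.integer(tab)
  out[order(out$c_call, -out$count), , drop = FALSE]
}

#' Explain one observed marker vector
#'
#' Minimal explanation under the preference order
#' allele > exon_swap > recombinant > novel:
#' \itemize{
#'   \item \code{allele}: exact match to a germline allele vector.
#'   \item \code{exon_swap}: exon-1 marker block from one allele and exon-3
#'     block from another, both blocks internally intact.
#'   \item \code{recombinant}: product of a single crossover within exon 1
#'     between two alleles (cross-isotype donors allowed); the breakpoint is
#'     reported as the maximal marker interval compatible with the data —
#'     from the last marker that must come from the left donor to the first
#'     marker that must come from the right donor.
#'   \item \code{novel}: anything requiring two or more switches.
#' }
#'
#' @param vector character vector of observed bases at the marker positions
#'   (or a single collapsed string); `N` entries match nothing.
#' @param locus a `trb_locus` (its allele table is the allele set).
#' @return list with `class`, `donors` (allele names; length 1 or 2),
#'   `breakpoint_lo`, `breakpoint_hi` (marker indices bounding the crossover
#'   interval; `NA` unless recombinant).
#' @export
explain_variant <- function(vector, locus) {
  if (length(vector) == 1L && nchar(vector[1L]) > 1L) vector <- chars(vector)
  ab <- locus$allele_bases
  n_mk <- nrow(ab)
  if (length(vector) != n_mk)
    stop("marker vector length must equal the marker table", call. = FALSE)
  alleles <- colnames(ab)
  exon1 <- which(locus$markers$region == locus$markers$region[1L])
  ex3 <- setdiff(seq_len(n_mk), exon1)

  hit <- alleles[vapply(alleles, function(a) all(vector == ab[, a]),
                        logical(1))]
  if (length(hit))
    return(list(class = "allele", donors = hit[1L],
                breakpoint_lo = NA_integer_, breakpoint_hi = NA_integer_))

  if (length(ex3)) {
    m1 <- alleles[vapply(alleles, function(a)
      all(vector[exon1] == ab[exon1, a]), logical(1))]
    m3 <- alleles[vapply(alleles, function(a)
      all(vector[ex3] == ab[ex3, a]), logical(1))]
    for (x in m1) for (y in m3) if (x != y)
      return(list(class = "exon_swap", donors = c(x, y),
                  breakpoint_lo = NA_integer_, breakpoint_hi = NA_integer_))
  }

  k_max <- max(exon1) - 1L
  for (a in alleles) for (b in alleles) {
    if (a == b) next
    ks <- Filter(function(k) all(vector[seq_len(k)] == ab[seq_len(k), a]) &&
                   all(vector[(k + 1L):n_mk] == ab[(k + 1L):n_mk, b]),
                 seq_len(k_max))
    if (length(ks))
      return(list(class = "recombinant", donors = c(a, b),
                  breakpoint_lo = min(ks), breakpoint_hi = max(ks) + 1L))
  }
  list(class = "novel", donors = character(),
       breakpoint_lo = NA_integer_, breakpoint_hi = NA_integer_)
}

#' Explain every distinct marker vector of a repertoire
#'
#' Runs [collect_marker_vectors()] and [explain_variant()] and returns the
#' census with explanations, one row per distinct (grouping, isotype,
#' vector).
#'
#' @inheritParams collect_marker_vectors
#' @param locus a `trb_locus`.
#' @return the vector census with `class`, `donors` and
#'   `breakpoint_lo`/`breakpoint_hi` columns appended.
#' @export
explain_repertoire_variants <- function(records, locus, by = character()) {
  census <- collect_marker_vectors(records, by = by)
  ex <- lapply(census$vector, explain_variant, locus = locus)
  census$class <- vapply(ex, `[[`, character(1), "class")
  census$donors <- vapply(ex, function(e) paste(e$donors, collapse = "+"),
                          character(1))
  census$breakpoint_lo <- vapply(ex, `[[`, integer(1), "breakpoint_lo")
  census$breakpoint_hi <- vapply(ex, `[[`, integer(1), "breakpoint_hi")
  rownames(census) <- NULL
  census
}
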