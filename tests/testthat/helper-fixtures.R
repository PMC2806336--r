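# Shared fixtures and independent oracles for the test suite.

.fixture_env <- new.env(parent = emptyenv())

# The packaged sheep-shaped locus, built once per test run.
shared_locus <- function() {
  if (is.null(.fixture_env$locus)) .fixture_env$locus <- make_fixture_locus()
  .fixture_env$locus
}

# Smallest legal locus: one cluster, one D/J/C, no markers beyond a pair.
minimal_locus <- function() {
  j_seq <- paste0("CAGGCTGCTCAT", "TTTGGACAAGGG", "GCTGCTCATCAT")  # phe at 13
  trb_locus(
    clusters = data.frame(cluster_id = "clusterA", genomic_rank = 1L,
                          d_gene = "D_A", c_gene = "C_A",
                          stringsAsFactors = FALSE),
    j_genes = list(clusterA = "J_A"),
    seqs = c(D_A = "GGGACAGGGGGC", J_A = j_seq,
             C_A = paste(rep("GCAGTTCCTACG", 5L), collapse = "")),
    kinds = c(D_A = "D", J_A = "J", C_A = "C"),
    c_exons = data.frame(exon = "exon1", start = 1L, end = 60L,
                         stringsAsFactors = FALSE),
    j_phe = c(J_A = 13L),
    markers = data.frame(idx = integer(), region = character(),
                         position = integer()),
    allele_bases = matrix(character(), nrow = 0L, ncol = 0L),
    allele_isotype = stats::setNames(character(), character()),
    diagnostics = integer(),
    species = "minimal test locus"
  )
}

# Assemble a transcript from explicit parts against a locus.
build_transcript <- function(locus, v_end = "", n1 = "", d = "", n2 = "",
                             j_gene, j_trim = 0L, c_gene = NULL,
                             c_seq = NULL) {
  j_seq <- locus$seqs[[j_gene]]
  if (is.null(c_seq)) c_seq <- locus$seqs[[c_gene]]
  paste0(locus$anchor$nt, v_end, n1, d, n2,
         substr(j_seq, j_trim + 1L, nchar(j_seq)), c_seq)
}

# Independent J oracle: enumerate every (gene, trim) pair and keep exact
# suffix matches of the pre-constant region; the canonical answer is the
# pair with the longest match (minimal trim).
oracle_j <- function(region, locus, min_match = 6L) {
  best <- NULL
  for (nm in unlist(locus$j_genes, use.names = FALSE)) {
    j <- locus$seqs[[nm]]
    for (trim in 0:(nchar(j) - min_match)) {
      suf <- substr(j, trim + 1L, nchar(j))
      if (nchar(region) >= nchar(suf) &&
          substr(region, nchar(region) - nchar(suf) + 1L,
                 nchar(region)) == suf) {
        if (is.null(best) || nchar(suf) > best$len)
          best <- list(gene = nm, trim = trim, len = nchar(suf))
        break  # larger trims only shorten the match
      }
    }
  }
  best
}

# Independent D oracle: brute-force longest common substring between the
# central region and each germline D (enumeration, no seeding/extension).
oracle_d_lcs <- function(central, locus, min_run = 4L) {
  ord <- order(locus$clusters$genomic_rank)
  d_names <- locus$clusters$d_gene[ord]
  lens <- vapply(d_names, function(nm) {
    d <- locus$seqs[[nm]]
    best <- 0L
    for (i in seq_len(nchar(d))) for (jj in i:nchar(d)) {
      L <- jj - i + 1L
      if (L <= best) next
      if (grepl(substr(d, i, jj), central, fixed = TRUE)) best <- L
    }
    best
  }, integer(1))
  if (!length(lens) || max(lens) < min_run)
    return(list(gene = "none", len = 0L, tied = character()))
  tied <- d_names[lens == max(lens)]
  list(gene = if (length(tied) == 1L) tied else "none",
       len = max(lens), tied = tied)
}
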