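test_that("a zero-modification join recovers CDR3, J, C and empty N regions", {
  loc <- shared_locus()
  v <- loc$v_ends[[1L]]
  d <- loc$seqs[["TRBD1"]]
  tr <- build_transcript(loc, v_end = v, d = d, j_gene = "TRBJ1.1",
                         j_trim = 0L, c_gene = "TRBC1")
  ext <- extract_cdr3(tr, loc)
  expect_identical(ext$j_gene, "TRBJ1.1")
  expect_identical(ext$j_trim, 0L)
  expect_identical(ext$c_call$c_gene, "TRBC1")
  expect_identical(ext$c_call$status, "ok")
  phe <- loc$j_phe[["TRBJ1.1"]]
  anchor_tail <- substr(loc$anchor$nt, 10L, 18L)
  expect_identical(ext$cdr3_nt,
                   paste0(anchor_tail, v, d,
                          substr(loc$seqs[["TRBJ1.1"]], 1L, phe - 1L)))

  dc <- assign_d(ext$cdr3_nt, nchar(anchor_tail) + nchar(v),
                 nchar(ext$cdr3_nt) - (phe - 1L) + 1L, loc)
  expect_identical(dc$gene, "TRBD1")
  expect_identical(dc$five_prime_trim, 0L)
  expect_identical(dc$three_prime_trim, 0L)
  expect_identical(nrow(dc$substitutions), 0L)

  dec <- decompose_junction(ext$cdr3_nt, dc, ext$j_gene, ext$j_trim, loc)
  expect_identical(dec$v_retained, paste0(anchor_tail, v))
  expect_identical(dec$n1, "")
  expect_identical(dec$n2, "")
})

test_that("J trimming is recovered and agrees with the (gene x trim) suffix-scan oracle", {
  loc <- shared_locus()
  set.seed(42)
  cases <- expand.grid(j = c("TRBJ2.7", "TRBJ1.4", "TRBJ3.2"),
                       trim = c(0L, 3L, 7L, 12L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    j <- cases$j[i]; trim <- cases$trim[i]
    # N chosen so the base preceding the trimmed J cannot extend the match.
    nxt <- substr(loc$seqs[[j]], trim, trim)
    n2 <- paste0("CAG", setdiff(c("A", "C", "G", "T"), nxt)[1L])
    tr <- build_transcript(loc, v_end = loc$v_ends[[2L]],
                           d = loc$seqs[["TRBD3"]], n2 = n2,
                           j_gene = j, j_trim = trim, c_gene = "TRBC3")
    ext <- extract_cdr3(tr, loc)
    expect_identical(ext$j_gene, j)
    expect_identical(ext$j_trim, trim)
    region <- substr(tr, ext$anchor_end + 1L, ext$c_start - 1L)
    ora <- oracle_j(region, loc)
    expect_identical(ora$gene, ext$j_gene)
    expect_identical(ora$trim, ext$j_trim)
  }
})

test_that("anchor and J failure modes are explicit", {
  loc <- shared_locus()
  tr <- build_transcript(loc, v_end = loc$v_ends[[1L]],
                         j_gene = "TRBJ1.1", c_gene = "TRBC1")
  # No anchor at all.
  expect_error(extract_cdr3(substr(tr, 19L, nchar(tr)), loc), "anchor")
  # Two anchors.
  expect_error(extract_cdr3(paste0(loc$anchor$nt, tr), loc), "ambiguous")
  # No J: junction straight into the constant region.
  no_j <- paste0(loc$anchor$nt, "ACGTACGTACGT", loc$seqs[["TRBC1"]])
  expect_error(extract_cdr3(no_j, loc), "J suffix")
})

test_that("D assignment handles exact containment, ties and absence", {
  loc <- shared_locus()
  d1 <- loc$seqs[["TRBD1"]]
  # Exact containment.
  jx <- paste0("CC", d1, "GG")
  dc <- assign_d(jx, 0L, nchar(jx) + 1L, loc)
  expect_identical(dc$gene, "TRBD1")
  expect_identical(dc$five_prime_trim, 0L)
  expect_identical(dc$three_prime_trim, 0L)

  # A constructed tie: equal-length best runs from two D genes. The helper
  # oracle confirms the construction before the assertion.
  d3 <- loc$seqs[["TRBD3"]]
  found <- FALSE
  for (sep in c("A", "C", "G", "T")) {
    filler <- strrep(sep, 3L)
    cand <- paste0(filler, substr(d1, 5L, 9L), filler,
                   substr(d3, 4L, 8L), filler)
    ora <- oracle_d_lcs(cand, loc)
    if (ora$len == 5L && setequal(ora$tied, c("TRBD1", "TRBD3"))) {
      found <- TRUE
      tie_none <- assign_d(cand, 0L, nchar(cand) + 1L, loc,
                           tie_policy = "none")
      expect_identical(tie_none$gene, "none")
      expect_setequal(tie_none$candidates, c("TRBD1", "TRBD3"))
      tie_prio <- assign_d(cand, 0L, nchar(cand) + 1L, loc,
                           tie_policy = "priority")
      expect_identical(tie_prio$gene, "TRBD1")  # genomic order D1 > D3 > D2
      break
    }
  }
  expect_true(found)

  # Absence of D is a valid outcome, not an error.
  none <- assign_d("AAAA", 0L, 5L, loc, min_run = 5L)
  expect_identical(none$gene, "none")
  expect_identical(none$candidates, character())
})

test_that("assign_d (extension off) equals the brute-force LCS oracle and is monotone in min_run", {
  loc <- shared_locus()
  set.seed(7)
  for (i in 1:300) {
    len <- sample(8:60, 1L)
    jx <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    got4 <- assign_d(jx, 0L, len + 1L, loc, min_run = 4L,
                     extend_subs = FALSE)
    ora4 <- oracle_d_lcs(jx, loc, min_run = 4L)
    expect_identical(got4$gene, ora4$gene)
    if (got4$gene != "none")
      expect_identical(nchar(got4$matched), ora4$len)
    # Monotonicity: raising min_run never converts none into a call.
    got6 <- assign_d(jx, 0L, len + 1L, loc, min_run = 6L,
                     extend_subs = FALSE)
    if (got4$gene == "none" && length(got4$candidates) == 0L)
      expect_identical(got6$gene, "none")
  }
})

test_that("substitution extension records deviations instead of absorbing them", {
  loc <- shared_locus()
  d1 <- chars(loc$seqs[["TRBD1"]])
  pos <- 5L
  obs <- setdiff(c("A", "C", "G", "T"), d1[pos])[1L]
  mutated <- d1
  mutated[pos] <- obs
  jx <- paste0("CCC", paste(mutated, collapse = ""), "GGG")
  dc <- assign_d(jx, 0L, nchar(jx) + 1L, loc, extend_subs = TRUE)
  expect_identical(dc$gene, "TRBD1")
  expect_identical(dc$five_prime_trim, 0L)
  expect_identical(dc$three_prime_trim, 0L)
  expect_identical(dc$substitutions$offset, pos)
  expect_identical(dc$substitutions$ref, d1[pos])
  expect_identical(dc$substitutions$obs, obs)
  # Matched length equals germline length minus trims (no indels).
  expect_identical(nchar(dc$matched), length(d1))

  # With extension off the seed stops at the substitution.
  dc0 <- assign_d(jx, 0L, nchar(jx) + 1L, loc, extend_subs = FALSE)
  expect_identical(dc0$gene, "TRBD1")
  expect_lt(nchar(dc0$matched), length(d1))
})

test_that("CDR3 length follows the post-cysteine-to-pre-phenylalanine convention", {
  loc <- shared_locus()
  v <- loc$v_ends[[1L]]
  d <- loc$seqs[["TRBD1"]]
  tr <- build_transcript(loc, v_end = v, d = d, j_gene = "TRBJ1.1",
                         c_gene = "TRBC1")
  ext <- extract_cdr3(tr, loc)
  n_nt <- nchar(ext$cdr3_nt)
  if (n_nt %% 3L == 0L) {
    expect_identical(cdr3_length(ext), n_nt %/% 3L)
    expect_identical(nchar(ext$cdr3_aa), n_nt %/% 3L)
  } else {
    expect_error(cdr3_length(ext), "frame")
  }

  # An empty CDR3 is legal when the anchor motif ends at the cysteine and
  # the J is trimmed up to its phenylalanine codon.
  loc0 <- loc
  loc0$anchor <- list(motif = "YLC", cys_index = 3L, nt = "TATCTCTGT")
  phe <- loc0$j_phe[["TRBJ1.1"]]
  tr0 <- build_transcript(loc0, j_gene = "TRBJ1.1", j_trim = phe - 1L,
                          c_gene = "TRBC1")
  ext0 <- extract_cdr3(tr0, loc0)
  expect_identical(ext0$cdr3_nt, "")
  expect_identical(cdr3_length(ext0), 0L)
})

test_that("reconstruction identity holds on noisy simulated junctions", {
  loc <- shared_locus()
  cfg <- sim_config(loc)
  sim <- simulate_repertoire(cfg, 200, seed = 19)
  ann <- annotate_transcripts(sim$sequences, loc)
  expect_true(all(is.na(ann$fail_reason)))
  recon <- paste0(ann$v_retained, ann$np1, ann$d_observed, ann$np2,
                  vapply(seq_len(nrow(ann)), function(i) {
                    j <- ann$j_call[i]
                    phe <- loc$j_phe[[j]]
                    keep <- max(0L, phe - 1L - ann$j_5p_trim[i])
                    if (keep == 0L) "" else
                      substr(loc$seqs[[j]], phe - keep, phe - 1L)
                  }, character(1)))
  expect_identical(recon, ann$junction)
})

test_that("zero-noise simulation round trip is lossless on every field", {
  loc <- shared_locus()
  cfg <- sim_config(loc, trim_max = c(v = 0L, j = 0L), d_keep_min = 99L,
                    n_mean = c(n1 = 0, n2 = 0), n_no_d_mean = 0,
                    subst_rate = 0, exon_swap_rate = 0, recomb_rate = 0,
                    nonproductive_fraction = NA)
  sim <- simulate_repertoire(cfg, 150, seed = 5)
  ann <- annotate_transcripts(sim$sequences, loc)
  tr <- sim$truth
  expect_true(all(is.na(ann$fail_reason)))
  expect_identical(ann$j_call, tr$j_gene)
  expect_identical(ann$j_5p_trim, tr$j_5p_trim)
  expect_identical(ann$d_call, tr$d_gene)
  d <- tr$d_gene != "none"
  expect_identical(ann$d_5p_trim[d], tr$d_5p_trim[d])
  expect_identical(ann$d_3p_trim[d], tr$d_3p_trim[d])
  expect_identical(ann$v_retained, tr$v_retained)
  expect_identical(ann$np1, tr$n1)
  expect_identical(ann$np2, tr$n2)
  expect_identical(ann$junction, tr$junction)
  expect_identical(ann$c_call, tr$c_gene)
  expect_identical(ann$c_marker_vector, tr$c_marker_vector)
  expect_identical(ann$productive, tr$productive)
})
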