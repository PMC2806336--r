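# Cluster topology: genomic order cluster1 < cluster3 < cluster2, so the
# full truth tables for the sheep instance are fixed by the layout alone.

test_that("rearrangement and splice classes follow the full topology truth tables", {
  loc <- shared_locus()
  rearr_expected <- list(
    c("cluster1", "cluster1", "intra_cluster"),
    c("cluster3", "cluster3", "intra_cluster"),
    c("cluster2", "cluster2", "intra_cluster"),
    c("cluster1", "cluster3", "inter_cluster"),   # D1-J3
    c("cluster1", "cluster2", "inter_cluster"),   # D1-J2
    c("cluster3", "cluster2", "inter_cluster"),   # D3-J2
    c("cluster3", "cluster1", "trans_rearrangement"),  # D3-J1
    c("cluster2", "cluster3", "trans_rearrangement"),  # D2-J3
    c("cluster2", "cluster1", "trans_rearrangement"))  # D2-J1
  for (row in rearr_expected)
    expect_identical(classify_rearrangement(row[1L], row[2L], loc), row[3L])
  expect_identical(classify_rearrangement(NA_character_, "cluster1", loc),
                   "no_d")
  expect_error(classify_rearrangement("clusterX", "cluster1", loc),
               "clusterX")

  splice_expected <- list(
    c("cluster1", "cluster1", "canonical"),
    c("cluster3", "cluster3", "canonical"),
    c("cluster2", "cluster2", "canonical"),
    c("cluster1", "cluster3", "cis_splice"),    # J1-C3
    c("cluster1", "cluster2", "cis_splice"),    # J1-C2
    c("cluster3", "cluster2", "cis_splice"),    # J3-C2
    c("cluster3", "cluster1", "trans_splice"),  # J3-C1
    c("cluster2", "cluster1", "trans_splice"),  # J2-C1
    c("cluster2", "cluster3", "trans_splice"))  # J2-C3
  for (row in splice_expected)
    expect_identical(classify_splice(row[1L], row[2L], loc), row[3L])
  expect_error(classify_splice("cluster1", "clusterX", loc), "clusterX")
})

test_that("the packaged clone table yields the published event census", {
  loc <- shared_locus()
  tab <- classify_events(load_clone_table(), loc)
  expect_identical(nrow(tab), 72L)

  rearr <- table(tab$rearrangement_class)
  expect_identical(as.integer(rearr[c("intra_cluster", "inter_cluster",
                                      "trans_rearrangement", "no_d")]),
                   c(25L, 32L, 3L, 12L))
  # Intra breakdown: 10 D1-J1, 9 D3-J3, 6 D2-J2.
  intra <- tab[tab$rearrangement_class == "intra_cluster", ]
  expect_identical(sum(intra$d_gene == "TRBD1"), 10L)
  expect_identical(sum(intra$d_gene == "TRBD3"), 9L)
  expect_identical(sum(intra$d_gene == "TRBD2"), 6L)
  # Inter breakdown: 20 D1-J2, 6 D1-J3, 6 D3-J2.
  inter <- tab[tab$rearrangement_class == "inter_cluster", ]
  inter_dj <- paste(inter$d_gene, substr(inter$j_gene, 1L, 5L))
  expect_identical(sum(inter_dj == "TRBD1 TRBJ2"), 20L)
  expect_identical(sum(inter_dj == "TRBD1 TRBJ3"), 6L)
  expect_identical(sum(inter_dj == "TRBD3 TRBJ2"), 6L)
  # The three trans-rearranged clones, by name.
  expect_setequal(
    tab$clone_id[tab$rearrangement_class == "trans_rearrangement"],
    c("pSTMos.23", "pSTA.09", "pSSAR.08"))

  spl <- table(tab$splice_class)
  expect_identical(as.integer(spl[c("canonical", "cis_splice",
                                    "trans_splice")]),
                   c(49L, 7L, 16L))
  # Canonical: 10 J1-C1, 17 J3-C3, 22 J2-C2; cis: 4 J1-C3 + 3 J3-C2.
  can <- tab[tab$splice_class == "canonical", ]
  can_jc <- paste(substr(can$j_gene, 1L, 5L), can$c_gene)
  expect_identical(sum(can_jc == "TRBJ1 TRBC1"), 10L)
  expect_identical(sum(can_jc == "TRBJ3 TRBC3"), 17L)
  expect_identical(sum(can_jc == "TRBJ2 TRBC2"), 22L)
  cis <- tab[tab$splice_class == "cis_splice", ]
  cis_jc <- paste(substr(cis$j_gene, 1L, 5L), cis$c_gene)
  expect_identical(sum(cis_jc == "TRBJ1 TRBC3"), 4L)
  expect_identical(sum(cis_jc == "TRBJ3 TRBC2"), 3L)
  # Trans splices all carry a J2 gene with C3 or C1.
  tsp <- tab[tab$splice_class == "trans_splice", ]
  expect_true(all(substr(tsp$j_gene, 1L, 5L) == "TRBJ2"))
  expect_true(all(tsp$c_gene %in% c("TRBC1", "TRBC3")))
})

test_that("event classes partition any annotated repertoire", {
  loc <- shared_locus()
  cfg <- sim_config(loc)
  sim <- simulate_repertoire(cfg, 300, seed = 23)
  ann <- classify_events(annotate_transcripts(sim$sequences, loc), loc)
  ok <- is.na(ann$fail_reason)
  r <- ann$rearrangement_class[ok]
  s <- ann$splice_class[ok]
  expect_true(all(r %in% c("intra_cluster", "inter_cluster",
                           "trans_rearrangement", "no_d")))
  expect_true(all(s %in% c("canonical", "cis_splice", "trans_splice")))
  d_assigned <- ann$d_call[ok] != "none"
  expect_identical(sum(r == "no_d"), sum(!d_assigned))
  expect_identical(sum(table(r)), sum(ok))
  expect_identical(sum(table(s)), sum(ok))
})

test_that("isotype calling from diagnostic bases matches exhaustive enumeration", {
  loc <- shared_locus()
  diag_rows <- match(loc$diagnostics, loc$markers$idx)
  pos <- loc$markers$position[diag_rows]
  iso <- unique(loc$allele_isotype)
  diag_vec <- vapply(iso, function(ct) {
    al <- names(loc$allele_isotype)[loc$allele_isotype == ct][1L]
    paste(loc$allele_bases[diag_rows, al], collapse = "")
  }, character(1))

  base_c <- loc$seqs[["TRBC3"]]
  combos <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                        b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    s <- strsplit(base_c, "")[[1L]]
    s[pos] <- unlist(combos[i, ])
    res <- call_c_isotype(paste(s, collapse = ""), loc)
    expected <- iso[diag_vec == paste(combos[i, ], collapse = "")]
    if (length(expected) == 1L) {
      expect_identical(res$status, "ok")
      expect_identical(res$c_gene, expected)
    } else {
      expect_identical(res$status, "novel")
      expect_true(is.na(res$c_gene))
    }
  }

  # Truncated constant portion is an error, never a guess.
  expect_error(call_c_isotype(substr(loc$seqs[["TRBC1"]], 1L, max(pos) - 1L),
                              loc),
               "truncated")
})
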