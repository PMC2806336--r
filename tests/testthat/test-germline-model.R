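test_that("the packaged sheep-shaped locus has the expected census and topology", {
  loc <- shared_locus()
  expect_s3_class(loc, "trb_locus")
  expect_identical(unname(j_census(loc)), c(6L, 5L, 7L))
  expect_identical(names(j_census(loc)), c("cluster1", "cluster3", "cluster2"))
  expect_identical(sum(j_census(loc)), 18L)
  expect_identical(sum(loc$genes$functional[loc$genes$kind == "J"]), 17L)
  expect_true(all(nchar(loc$seqs[loc$clusters$d_gene]) >= 12L))

  # Marker system: 12 exon-1 + 2 exon-3 positions, six replacement codons.
  expect_identical(sum(loc$markers$region == "exon1"), 12L)
  expect_identical(sum(loc$markers$region == "exon3"), 2L)
  exon1 <- loc$c_exons[loc$c_exons$exon == "exon1", ]
  aa_by_allele <- vapply(colnames(loc$allele_bases), function(al) {
    s <- strsplit(loc$seqs[[unname(loc$allele_isotype[al])]], "")[[1L]]
    s[loc$markers$position] <- loc$allele_bases[, al]
    trbrep:::translate_nt(paste(s[exon1$start:exon1$end], collapse = ""))
  }, character(1))
  aa_mat <- do.call(rbind, strsplit(aa_by_allele, ""))
  n_replacement <- sum(apply(aa_mat, 2L, function(col) length(unique(col)) > 1L))
  expect_identical(n_replacement, 6L)

  # Isotype diagnostics distinguish the three C genes.
  diag_rows <- match(loc$diagnostics, loc$markers$idx)
  dvec <- vapply(unique(loc$allele_isotype), function(ct) {
    al <- names(loc$allele_isotype)[loc$allele_isotype == ct][1L]
    paste(loc$allele_bases[diag_rows, al], collapse = "")
  }, character(1))
  expect_identical(anyDuplicated(dvec), 0L)
})

test_that("upstream_of is a strict total order consistent with genomic rank", {
  loc <- shared_locus()
  ids <- loc$clusters$cluster_id
  expect_true(upstream_of(loc, "cluster1", "cluster3"))
  expect_true(upstream_of(loc, "cluster3", "cluster2"))
  expect_false(upstream_of(loc, "cluster2", "cluster3"))
  for (a in ids) expect_false(upstream_of(loc, a, a))  # irreflexive
  for (a in ids) for (b in ids) if (a != b) {
    expect_identical(upstream_of(loc, a, b), !upstream_of(loc, b, a))
    for (cc in ids) if (upstream_of(loc, a, b) && upstream_of(loc, b, cc))
      expect_true(upstream_of(loc, a, cc))  # transitive
  }
  expect_error(upstream_of(loc, "cluster1", "cluster9"), "cluster9")
})

test_that("layout + FASTA round trip reproduces the model exactly", {
  loc <- shared_locus()
  layout <- tempfile(fileext = ".yaml")
  fasta <- tempfile(fileext = ".fasta")
  write_locus(loc, layout, fasta)
  loc2 <- load_locus(layout, fasta)
  expect_identical(loc2$seqs[names(loc$seqs)], loc$seqs)
  expect_identical(loc2$clusters, loc$clusters)
  expect_identical(loc2$j_genes, loc$j_genes)
  expect_identical(loc2$j_phe[names(loc$j_phe)], loc$j_phe)
  expect_equal(loc2$markers, loc$markers, ignore_attr = TRUE)
  expect_identical(loc2$allele_bases[, colnames(loc$allele_bases)],
                   loc$allele_bases)
  expect_identical(loc2$allele_isotype, loc$allele_isotype)
  expect_identical(loc2$diagnostics, loc$diagnostics)
  expect_identical(loc2$v_ends, loc$v_ends)
  expect_identical(loc2$anchor$nt, loc$anchor$nt)
  expect_equal(loc2$genes[order(loc2$genes$name), ],
               loc$genes[order(loc$genes$name), ], ignore_attr = TRUE)
})

test_that("a minimal single-cluster locus is legal", {
  loc <- minimal_locus()
  expect_s3_class(loc, "trb_locus")
  expect_identical(unname(j_census(loc)), 1L)
})

test_that("malformed inputs are rejected with informative errors", {
  loc <- shared_locus()
  layout <- tempfile(fileext = ".yaml")
  fasta <- tempfile(fileext = ".fasta")
  write_locus(loc, layout, fasta)

  # A layout naming a J gene absent from the FASTA.
  y <- yaml::read_yaml(layout)
  y$clusters[[2L]]$j_genes <- c(y$clusters[[2L]]$j_genes, "TRBJ9.9")
  bad_layout <- tempfile(fileext = ".yaml")
  yaml::write_yaml(y, bad_layout)
  expect_error(load_locus(bad_layout, fasta), "TRBJ9.9")

  # Non-ACGT character, with its position.
  seqs <- loc$seqs
  seqs[["TRBD1"]] <- sub("A", "X", seqs[["TRBD1"]])
  expect_error(
    trb_locus(loc$clusters, loc$j_genes, seqs,
              stats::setNames(loc$genes$kind, loc$genes$name),
              c_exons = loc$c_exons, j_phe = loc$j_phe,
              markers = loc$markers, allele_bases = loc$allele_bases,
              allele_isotype = loc$allele_isotype,
              diagnostics = loc$diagnostics, v_ends = loc$v_ends),
    "non-ACGT character at position")

  # Duplicate gene assignment (one J in two clusters).
  jg <- loc$j_genes
  jg$cluster1 <- c(jg$cluster1, "TRBJ2.1")
  expect_error(
    trb_locus(loc$clusters, jg, loc$seqs,
              stats::setNames(loc$genes$kind, loc$genes$name),
              c_exons = loc$c_exons, j_phe = loc$j_phe,
              markers = loc$markers, allele_bases = loc$allele_bases,
              allele_isotype = loc$allele_isotype,
              diagnostics = loc$diagnostics, v_ends = loc$v_ends),
    "more than one cluster")

  # Ranks must be a permutation.
  cl <- loc$clusters
  cl$genomic_rank <- c(1L, 1L, 3L)
  expect_error(
    trb_locus(cl, loc$j_genes, loc$seqs,
              stats::setNames(loc$genes$kind, loc$genes$name),
              c_exons = loc$c_exons, j_phe = loc$j_phe,
              markers = loc$markers, allele_bases = loc$allele_bases,
              allele_isotype = loc$allele_isotype,
              diagnostics = loc$diagnostics, v_ends = loc$v_ends),
    "permutation")
})

test_that("distinct seeds give distinct sequences over identical topology", {
  a <- make_fixture_locus(seed = 101L)
  b <- make_fixture_locus(seed = 202L)
  expect_false(identical(a$seqs, b$seqs))
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$j_genes, b$j_genes)
  expect_identical(a$markers, b$markers)
  expect_identical(a$allele_bases, b$allele_bases)
  # And the same seed reproduces byte-identically.
  expect_identical(make_fixture_locus(seed = 101L)$seqs, a$seqs)
})
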