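# Synthetic sheep-shaped fixture locus.
#
# The packaged locus reproduces the ruminant topology — three D-J-C clusters
# in genomic order cluster1 < cluster3 < cluster2, J census 6/5/7, three
# highly similar C isotypes — with deterministic, seed-derived nucleotide
# sequences. It is a synthetic stand-in: topology, gene census and the
# marker-system structure are faithful (14 variable constant-region
# positions, 12 in exon 1 and 2 in exon 3, six of them non-synonymous,
# N-terminal isotype diagnostics), the sequences themselves are invented.

random_codons <- function(n) paste(sample(NONSTOP_CODONS, n, replace = TRUE),
                                   collapse = "")

# Marker design, fixed across seeds (the seed varies only the background).
# Columns are the six constant-region alleles, two per isotype. Markers 1-3
# are the N-terminal isotype diagnostics: marker 1 (third position of codon
# 1, silent) separates TRBC2 from TRBC1/TRBC3; markers 2 and 3 (codons 3 and
# 4, replacement) separate TRBC1 from TRBC2/TRBC3.
fixture_marker_design <- function() {
  allele_names <- c("TRBC1*01", "TRBC1*02", "TRBC2*01", "TRBC2*02",
                    "TRBC3*01", "TRBC3*02")
  bases <- rbind(
    c("A", "A", "G", "G", "A", "A"),  # M1  codon 1  pos3 silent (diag)
    c("A", "A", "C", "C", "C", "C"),  # M2  codon 3  pos2 replacement (diag)
    c("G", "G", "T", "T", "T", "T"),  # M3  codon 4  pos2 replacement (diag)
    c("C", "T", "C", "T", "C", "T"),  # M4  codon 6  pos2 replacement
    c("A", "A", "A", "A", "G", "G"),  # M5  codon 9  pos2 replacement
    c("G", "G", "T", "T", "G", "G"),  # M6  codon 12 pos2 replacement
    c("A", "G", "A", "G", "A", "G"),  # M7  codon 15 pos2 replacement
    c("T", "T", "T", "T", "T", "C"),  # M8  codon 18 pos3 silent
    c("C", "C", "A", "A", "C", "C"),  # M9  codon 21 pos3 silent
    c("G", "A", "G", "A", "G", "A"),  # M10 codon 24 pos3 silent
    c("T", "T", "C", "C", "T", "T"),  # M11 codon 27 pos3 silent
    c("A", "A", "A", "G", "A", "A"),  # M12 codon 30 pos3 silent
    c("A", "C", "A", "C", "G", "T"),  # M13 codon 53 pos3 silent (exon 3)
    c("A", "C", "C", "A", "G", "T")   # M14 codon 57 pos3 silent (exon 3)
  )
  colnames(bases) <- allele_names
  # (codon, position-in-codon) per marker; fixed codon prefixes keep silent
  # markers fourfold-degenerate and replacement markers stop-free.
  slots <- data.frame(
    idx = 1:14,
    codon = c(1L, 3L, 4L, 6L, 9L, 12L, 15L, 18L, 21L, 24L, 27L, 30L, 53L, 57L),
    in_codon = c(3L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 3L)
  )
  slots$position <- (slots$codon - 1L) * 3L + slots$in_codon
  slots$region <- ifelse(slots$codon <= 40L, "exon1", "exon3")
  # Fixed partial codons at marker slots (the marker base completes them).
  fixed <- list(`1` = c("G", "C", NA), `3` = c("C", NA, "C"),
                `4` = c("G", NA, "A"), `6` = c("C", NA, "G"),
                `9` = c("G", NA, "C"), `12` = c("C", NA, "A"),
                `15` = c("G", NA, "G"), `18` = c("G", "T", NA),
                `21` = c("G", "C", NA), `24` = c("C", "T", NA),
                `27` = c("A", "C", NA), `30` = c("C", "C", NA),
                `53` = c("T", "C", NA), `57` = c("G", "G", NA))
  list(allele_names = allele_names, bases = bases, slots = slots,
       fixed = fixed,
       isotype = stats::setNames(rep(c("TRBC1", "TRBC2", "TRBC3"), each = 2L),
                                 allele_names))
}

# Any substring of length L shared between two strings?
shares_kmer <- function(a, b, L) {
  if (nchar(a) < L || nchar(b) < L) return(FALSE)
  ka <- substring(a, seq_len(nchar(a) - L + 1L), seq(L, nchar(a)))
  kb <- substring(b, seq_len(nchar(b) - L + 1L), seq(L, nchar(b)))
  any(ka %in% kb)
}

#' Generate the synthetic sheep-shaped fixture locus
#'
#' Deterministically (from `seed`) builds a locus with the ruminant three-
#' cluster topology: clusters `cluster1`, `cluster3`, `cluster2` in genomic
#' order, J census 6/5/7 (17 of the 18 J genes functional), one D gene per
#' cluster (>= 12 nt), three C isotypes realized over a shared backbone that
#' differs only at 14 marker positions (12 in exon 1, 2 in exon 3; six
#' replacement markers, all in exon 1), two alleles per isotype, N-terminal
#' isotype diagnostics, four germline V-end suffixes and the YLCASS anchor.
#' Different seeds give different sequences over identical topology.
#'
#' @param seed integer seed for the background sequences.
#' @return a validated `trb_locus`.
#' @export
make_fixture_locus <- function(seed = 101L) {
  with_seed(seed, {
    des <- fixture_marker_design()

    # D genes: one per cluster, no shared >= 5 nt substring across genes so
    # that minimum-run assignment stays unambiguous above the 4 nt rule.
    d_len <- c(TRBD1 = 16L, TRBD3 = 15L, TRBD2 = 17L)
    repeat {
      d_seqs <- vapply(d_len, random_dna, character(1))
      pairs <- utils::combn(names(d_len), 2L)
      ok <- !any(apply(pairs, 2L, function(p)
        shares_kmer(d_seqs[[p[1L]]], d_seqs[[p[2L]]], 5L)))
      if (ok) break
    }

    # J genes: CDR3-contributing prefix, FGXG, 15 nt tail; codons aligned to
    # the phenylalanine so productive junctions stay stop-free; pairwise
    # common suffixes kept short so suffix matching cannot tie.
    j_names <- c(paste0("TRBJ1.", 1:6), paste0("TRBJ3.", 1:5),
                 paste0("TRBJ2.", 1:7))
    make_j <- function() {
      pre_len <- sample(13:20, 1L)
      pre <- random_codons(7L)
      pre <- substr(pre, nchar(pre) - pre_len + 1L, nchar(pre))
      x <- sample(setdiff(NONSTOP_CODONS, c("GGA", "GGC", "GGG", "GGT")), 1L)
      fgxg <- paste0(sample(c("TTT", "TTC"), 1L),
                     sample(c("GGA", "GGC", "GGG", "GGT"), 1L), x,
                     sample(c("GGA", "GGC", "GGG", "GGT"), 1L))
      list(seq = paste0(pre, fgxg, random_codons(5L)), phe = pre_len + 1L)
    }
    repeat {
      js <- lapply(j_names, function(nm) make_j())
      names(js) <- j_names
      seqs <- vapply(js, `[[`, character(1), "seq")
      pairs <- utils::combn(j_names, 2L)
      ok <- all(apply(pairs, 2L, function(p)
        common_suffix_len(seqs[[p[1L]]], seqs[[p[2L]]]) <= 4L))
      if (ok) break
    }
    j_seqs <- vapply(js, `[[`, character(1), "seq")
    j_phe <- vapply(js, function(x) as.integer(x$phe), integer(1))

    # Constant-region backbone: 70 sense codons (exon1 1-120, exon2 121-150,
    # exon3 151-210); marker slots get their fixed partial codons, isotypes
    # and alleles differ only at the 14 marker positions.
    backbone <- chars(random_codons(70L))
    for (i in seq_len(nrow(des$slots))) {
      sl <- des$slots[i, ]
      fx <- des$fixed[[as.character(sl$codon)]]
      for (p in 1:3)
        if (!is.na(fx[p])) backbone[(sl$codon - 1L) * 3L + p] <- fx[p]
    }
    realize_allele <- function(allele) {
      s <- backbone
      s[des$slots$position] <- des$bases[, allele]
      paste(s, collapse = "")
    }
    c_seqs <- c(TRBC1 = realize_allele("TRBC1*01"),
                TRBC2 = realize_allele("TRBC2*01"),
                TRBC3 = realize_allele("TRBC3*01"))

    v_ends <- replicate(4L, random_codons(3L))
    while (anyDuplicated(v_ends) || anyDuplicated(substr(v_ends, 1L, 2L)))
      v_ends <- replicate(4L, random_codons(3L))

    seqs <- c(d_seqs, j_seqs, c_seqs)
    kinds <- stats::setNames(c(rep("D", 3L), rep("J", 18L), rep("C", 3L)),
                             names(seqs))
    functional <- stats::setNames(rep(TRUE, length(seqs)), names(seqs))
    functional["TRBJ1.3"] <- FALSE  # synthetic pseudogene: 17/18 J functional

    trb_locus(
      clusters = data.frame(
        cluster_id = c("cluster1", "cluster3", "cluster2"),
        genomic_rank = c(1L, 2L, 3L),
        d_gene = c("TRBD1", "TRBD3", "TRBD2"),
        c_gene = c("TRBC1", "TRBC3", "TRBC2"),
        stringsAsFactors = FALSE),
      j_genes = list(cluster1 = paste0("TRBJ1.", 1:6),
                     cluster3 = paste0("TRBJ3.", 1:5),
                     cluster2 = paste0("TRBJ2.", 1:7)),
      seqs = seqs, kinds = kinds, functional = functional,
      c_exons = data.frame(exon = c("exon1", "exon2", "exon3"),
                           start = c(1L, 121L, 151L),
                           end = c(120L, 150L, 210L),
                           stringsAsFactors = FALSE),
      j_phe = j_phe,
      markers = des$slots[, c("idx", "region", "position")],
      allele_bases = des$bases,
      allele_isotype = des$isotype,
      diagnostics = 1:3,
      v_ends = v_ends,
      species = "synthetic sheep-like",
      provenance = sprintf("trbrep synthetic fixture, seed %d", seed)
    )
  })
}
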