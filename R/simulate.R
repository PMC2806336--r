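# Seeded synthetic-repertoire generator with per-transcript ground truth.
#
# Emulates the generative processes the analysis assumes: cluster-aware D-J
# joining with configurable intra/inter/trans-rearrangement mixture,
# truncated-geometric exonuclease trimming at 3'V, 5'D, 3'D and 5'J,
# Poisson N-nucleotide addition, rare substitutions inside the retained D,
# canonical/cis/trans J-to-C splicing, and biallelic constant genes subject
# to exon-swap (alternative splicing of exon 3) and single-crossover
# recombinational diversification over the marker system.

#' Build and validate a simulation configuration
#'
#' Defaults are the study regime the packaged clone table reflects: observed
#' rearrangement-class mixture 25:32:3 (intra:inter:trans) over D-assigned
#' clones with a 12/72 no-D fraction, splice mixture 49:7:16 over all clones,
#' modest trimming and N-addition (N-D-N around 14-16 nt for D-bearing
#' clones, N around 8 nt for no-D clones), 1% substitution rate inside D,
#' and 5% exon-swap / 5% recombinant constant-region variants. The class
#' mixtures describe observed classes, so D-bearing clones retain at least
#' `d_keep_min` nucleotides of D.
#'
#' @param locus a `trb_locus`.
#' @param p_no_d fraction of clones without any D contribution (direct V-J).
#' @param rearr_probs named mixture over `intra`, `inter`, `trans` for
#'   D-bearing clones; must sum to 1.
#' @param splice_probs named mixture over `canonical`, `cis`, `trans`.
#' @param trim_p named success probabilities of the truncated-geometric trim
#'   distributions (`v`, `d5`, `d3`, `j`).
#' @param trim_max named caps for the `v` and `j` trims.
#' @param d_keep_min minimum retained D length in D-bearing clones.
#' @param n_mean Poisson means for N1/N2 in D-bearing clones.
#' @param n_no_d_mean Poisson mean of the single N region of no-D clones.
#' @param subst_rate per-base substitution rate inside the retained D.
#' @param exon_swap_rate,recomb_rate rates of constant-region exon-swap and
#'   single-crossover recombinant variants (remainder: plain alleles).
#' @param nonproductive_fraction fraction of emitted transcripts with an
#'   out-of-frame or stop-containing CDR3; `NA` disables frame filtering.
#' @return a validated config list (class `trb_sim_config`).
#' @export
sim_config <- function(locus,
                       p_no_d = 12 / 72,
                       rearr_probs = c(intra = 25, inter = 32, trans = 3) / 60,
                       splice_probs = c(canonical = 49, cis = 7, trans = 16) / 72,
                       trim_p = c(v = 0.35, d5 = 0.45, d3 = 0.45, j = 0.25),
                       trim_max = c(v = 9L, j = 15L),
                       d_keep_min = 6L,
                       n_mean = c(n1 = 2.5, n2 = 2.5),
                       n_no_d_mean = 8,
                       subst_rate = 0.01,
                       exon_swap_rate = 0.05,
                       recomb_rate = 0.05,
                       nonproductive_fraction = 0) {
  stopifnot(inherits(locus, "trb_locus"))
  rearr_probs <- rearr_probs[c("intra", "inter", "trans")]
  splice_probs <- splice_probs[c("canonical", "cis", "trans")]
  probs <- c(p_no_d, rearr_probs, splice_probs, subst_rate,
             exon_swap_rate, recomb_rate)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(rearr_probs) - 1) > 1e-8 || abs(sum(splice_probs) - 1) > 1e-8)
    stop("class mixtures must sum to 1", call. = FALSE)
  if (exon_swap_rate + recomb_rate > 1)
    stop("exon_swap_rate + recomb_rate must not exceed 1", call. = FALSE)

  # Feasibility: every (rearrangement, splice) class pair with positive
  # probability needs at least one (D cluster, J cluster, C cluster) triple
  # consistent with the locus topology.
  triples <- enumerate_class_triples(locus)
  rearr_classes <- c(names(rearr_probs)[rearr_probs > 0],
                     if (p_no_d > 0) "no_d")
  for (r in rearr_classes)
    for (s in names(splice_probs)[splice_probs > 0])
      if (nrow(triples[[r]][[s]]) == 0L)
        stop("infeasible class combination under this locus: ",
             r, " rearrangement with ", s, " splicing", call. = FALSE)

  structure(list(locus = locus, p_no_d = p_no_d, rearr_probs = rearr_probs,
                 splice_probs = splice_probs, trim_p = trim_p,
                 trim_max = trim_max, d_keep_min = as.integer(d_keep_min),
                 n_mean = n_mean, n_no_d_mean = n_no_d_mean,
                 subst_rate = subst_rate, exon_swap_rate = exon_swap_rate,
                 recomb_rate = recomb_rate,
                 nonproductive_fraction = nonproductive_fraction,
                 triples = triples),
            class = "trb_sim_config")
}

# For each rearrangement class x splice class, the data.frame of consistent
# (d_cluster, j_cluster, c_cluster) triples (d_cluster NA for no_d).
enumerate_class_triples <- function(locus) {
  cl <- locus$clusters$cluster_id
  rk <- stats::setNames(locus$clusters$genomic_rank, cl)
  res <- list()
  for (r in c("intra", "inter", "trans", "no_d")) {
    res[[r]] <- list()
    for (s in c("canonical", "cis", "trans")) {
      grid <- expand.grid(d = if (r == "no_d") NA_character_ else cl,
                          j = cl, c = cl, stringsAsFactors = FALSE)
      keep <- vapply(seq_len(nrow(grid)), function(i) {
        d <- grid$d[i]; j <- grid$j[i]; cc <- grid$c[i]
        ok_r <- switch(r,
                       intra = d == j,
                       inter = rk[[d]] < rk[[j]],
                       trans = rk[[d]] > rk[[j]],
                       no_d = TRUE)
        ok_s <- switch(s,
                       canonical = cc == j,
                       cis = rk[[cc]] > rk[[j]],
                       trans = rk[[cc]] < rk[[j]])
        isTRUE(ok_r) && isTRUE(ok_s)
      }, logical(1))
      res[[r]][[s]] <- grid[keep, , drop = FALSE]
    }
  }
  res
}

# Draw a constant-region variant for one transcript. Returns marker vector,
# class, donors and breakpoint. Only marker-visible events are labelled:
# crossovers are resampled until the product differs from every pure allele
# and both donors are informative on their side of the breakpoint.
draw_c_variant <- function(cfg, c_gene) {
  locus <- cfg$locus
  ab <- locus$allele_bases
  iso <- locus$allele_isotype
  own <- names(iso)[iso == c_gene]
  base <- if (length(own) == 1L) own else sample(own, 1L)
  exon1_idx <- which(locus$markers$region ==
                       locus$markers$region[1L])  # markers are ordered
  n_mk <- nrow(locus$markers)
  # Crossovers are drawn downstream of the isotype diagnostics so the
  # product keeps its N-terminal isotype assignment, as observed hybrids do.
  diag_rows <- match(locus$diagnostics, locus$markers$idx)
  k_min <- if (length(diag_rows)) max(diag_rows) else 1L
  u <- stats::runif(1L)
  if (u < cfg$recomb_rate && n_mk > 1L) {
    for (attempt in 1:50) {
      donor <- sample(setdiff(colnames(ab), base), 1L)
      diffs <- which(ab[, base] != ab[, donor])
      diffs1 <- intersect(diffs, exon1_idx)
      ks <- Filter(function(k) k >= k_min && any(diffs1 <= k) &&
                     any(diffs1 > k),
                   seq_len(max(exon1_idx) - 1L))
      if (length(ks) == 0L) next
      k <- if (length(ks) == 1L) ks else sample(ks, 1L)
      vec <- c(ab[seq_len(k), base], ab[(k + 1L):n_mk, donor])
      if (!any(apply(ab, 2L, identical, vec))) {
        return(list(vector = vec, class = "recombinant", allele = base,
                    donors = c(base, donor), breakpoint = k))
      }
    }
  } else if (u < cfg$recomb_rate + cfg$exon_swap_rate && n_mk > 1L &&
             length(exon1_idx) < n_mk) {
    donor <- sample(setdiff(colnames(ab), base), 1L)
    vec <- ab[, base]
    ex3 <- setdiff(seq_len(n_mk), exon1_idx)
    vec[ex3] <- ab[ex3, donor]
    if (!any(apply(ab, 2L, identical, unname(vec))))
      return(list(vector = unname(vec), class = "exon_swap", allele = base,
                  donors = c(base, donor), breakpoint = NA_integer_))
  }
  list(vector = unname(ab[, base]), class = "allele", allele = base,
       donors = base, breakpoint = NA_integer_)
}

# Realize a constant-region nucleotide sequence from a marker vector, on the
# isotype's scaffold.
realize_c_sequence <- function(locus, c_gene, marker_vec) {
  s <- chars(locus$seqs[[c_gene]])
  s[locus$markers$position] <- marker_vec
  paste(s, collapse = "")
}

#' Simulate a labelled TRB cDNA repertoire
#'
#' Draws `n` transcripts under the configured mixtures and noise model and
#' returns their sequences together with a full ground-truth table
#' (V-retained part, N1, D gene with trims and substitution positions, N2, J
#' gene with 5' trim, CDR3, rearrangement and splice class, C isotype,
#' allele, variant class and breakpoint). Identical `config` and `seed`
#' give byte-identical output.
#'
#' @param config a `trb_sim_config` from [sim_config()].
#' @param n number of transcripts.
#' @param seed mandatory integer seed.
#' @return list with `sequences` (named character vector), `truth`
#'   (data.frame, one row per transcript) and `config`.
#' @export
simulate_repertoire <- function(config, n, seed) {
  stopifnot(inherits(config, "trb_sim_config"))
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  locus <- config$locus
  anchor_nt <- locus$anchor$nt
  anchor_tail <- substr(anchor_nt, locus$anchor$cys_index * 3L + 1L,
                        nchar(anchor_nt))
  d_of <- stats::setNames(locus$clusters$d_gene, locus$clusters$cluster_id)
  c_of <- stats::setNames(locus$clusters$c_gene, locus$clusters$cluster_id)
  fn <- locus$genes$name[locus$genes$functional]

  with_seed(seed, {
    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      rearr <- if (stats::runif(1L) < config$p_no_d) "no_d" else
        sample(names(config$rearr_probs), 1L, prob = config$rearr_probs)
      splice <- sample(names(config$splice_probs), 1L,
                       prob = config$splice_probs)
      tri <- config$triples[[rearr]][[splice]]
      pick <- tri[sample.int(nrow(tri), 1L), ]
      j_pool <- intersect(locus$j_genes[[pick$j]], fn)
      j_gene <- if (length(j_pool) == 1L) j_pool else sample(j_pool, 1L)
      d_gene <- if (rearr == "no_d") NA_character_ else d_of[[pick$d]]
      c_gene <- c_of[[pick$c]]

      cv <- draw_c_variant(config, c_gene)
      c_seq <- realize_c_sequence(locus, c_gene, cv$vector)

      want_np <- !is.na(config$nonproductive_fraction) &&
        stats::runif(1L) < config$nonproductive_fraction
      filter_on <- !is.na(config$nonproductive_fraction)

      j_seq <- locus$seqs[[j_gene]]
      phe <- locus$j_phe[[j_gene]]
      for (attempt in 1:1000) {
        v_label <- sample.int(length(locus$v_ends), 1L)
        v_end <- locus$v_ends[[v_label]]
        v_trim <- rtgeom(1L, config$trim_p[["v"]],
                         min(config$trim_max[["v"]], nchar(v_end)))
        v_kept <- substr(v_end, 1L, nchar(v_end) - v_trim)

        if (is.na(d_gene)) {
          n1 <- random_dna(stats::rpois(1L, config$n_no_d_mean))
          d_obs <- ""; n2 <- ""
          d5 <- NA_integer_; d3 <- NA_integer_; substs <- character()
        } else {
          d_seq <- locus$seqs[[d_gene]]
          d_len <- nchar(d_seq)
          d5 <- rtgeom(1L, config$trim_p[["d5"]], d_len - config$d_keep_min)
          d3 <- rtgeom(1L, config$trim_p[["d3"]],
                       d_len - config$d_keep_min - d5)
          core <- chars(substr(d_seq, d5 + 1L, d_len - d3))
          substs <- character()
          hit <- which(stats::runif(length(core)) < config$subst_rate)
          for (h in hit) {
            ref <- core[h]
            obs <- sample(setdiff(DNA_BASES, ref), 1L)
            core[h] <- obs
            substs <- c(substs, sprintf("%d:%s>%s", d5 + h, ref, obs))
          }
          d_obs <- paste(core, collapse = "")
          n1 <- random_dna(stats::rpois(1L, config$n_mean[["n1"]]))
          n2 <- random_dna(stats::rpois(1L, config$n_mean[["n2"]]))
        }
        j_trim <- rtgeom(1L, config$trim_p[["j"]],
                         min(config$trim_max[["j"]], phe - 1L))

        cdr3 <- paste0(anchor_tail, v_kept, n1, d_obs, n2,
                       substr(j_seq, j_trim + 1L, phe - 1L))
        in_frame <- nchar(cdr3) %% 3L == 0L
        productive <- in_frame && !grepl("*", translate_nt(
          if (in_frame) cdr3 else ""), fixed = TRUE)
        if (!filter_on || productive != want_np) break
      }
      transcript <- paste0(anchor_nt, v_kept, n1, d_obs, n2,
                           substr(j_seq, j_trim + 1L, nchar(j_seq)), c_seq)
      id <- sprintf("sim%05d", i)
      seqs[i] <- transcript
      rows[[i]] <- data.frame(
        sequence_id = id,
        v_end = sprintf("Vend%d", v_label), v_3p_trim = v_trim,
        v_retained = paste0(anchor_tail, v_kept),
        n1 = n1,
        d_gene = if (is.na(d_gene)) "none" else d_gene,
        d_5p_trim = d5, d_3p_trim = d3, d_observed = d_obs,
        d_substitutions = paste(substs, collapse = ","),
        n2 = n2,
        j_gene = j_gene, j_5p_trim = j_trim,
        junction = cdr3,
        junction_aa = if (nchar(cdr3) %% 3L == 0L) translate_nt(cdr3)
                      else NA_character_,
        productive = productive,
        rearrangement_class = c(intra = "intra_cluster",
                                inter = "inter_cluster",
                                trans = "trans_rearrangement",
                                no_d = "no_d")[[rearr]],
        splice_class = c(canonical = "canonical", cis = "cis_splice",
                         trans = "trans_splice")[[splice]],
        c_gene = c_gene, c_allele = cv$allele,
        c_variant_class = cv$class,
        c_donors = paste(cv$donors, collapse = "+"),
        c_breakpoint = cv$breakpoint,
        c_marker_vector = paste(cv$vector, collapse = ""),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    names(seqs) <- truth$sequence_id
    list(sequences = seqs, truth = truth, config = config)
  })
}

#' Write a simulated repertoire to FASTA plus truth TSV
#'
#' @param sim result of [simulate_repertoire()].
#' @param fasta_path,truth_path output paths.
#' @return the two paths, invisibly.
#' @export
write_repertoire <- function(sim, fasta_path, truth_path) {
  dna <- Biostrings::DNAStringSet(sim$sequences)
  Biostrings::writeXStringSet(dna, fasta_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, truth = truth_path))
}
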