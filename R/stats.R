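# Repertoire summary statistics.
#
# Gene-usage tables, CDR3-length statistics per tissue and per D group, and
# event-class fractions. Two reporting rules hold everywhere: percentages
# and means quoted to one decimal are obtained by truncation (the raw value
# is always emitted alongside, so every printed figure is recomputable from
# the counts), and every fraction carries its denominator explicitly —
# D-usage and rearrangement-class fractions are reported both over all
# clones and over the D-assigned subset, which differ.

#' Load the packaged cDNA clone annotation table
#'
#' 72 rearranged V-D-J-C beta-chain cDNA clones from four lymphoid tissues
#' (young thymus, adult thymus, spleen, blood) of three sheep breeds, with
#' their D/J/C gene assignments and CDR3 lengths (amino acids, counted from
#' after the conserved V cysteine to before the J FGXG phenylalanine). The
#' amino-acid columns are display transcriptions; computation uses the gene
#' calls and lengths.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame with one row per clone.
#' @export
load_clone_table <- function(path = system.file("extdata",
                                                "sheep_trb_cdna_clones.tsv",
                                                package = "trbrep")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

count_pct <- function(values, levels, denom) {
  n <- vapply(levels, function(l) sum(values == l, na.rm = TRUE), integer(1))
  data.frame(level = levels, n = n,
             proportion = n / denom, percent = pct1(n, denom),
             denominator = denom, stringsAsFactors = FALSE)
}

#' Summarize a repertoire
#'
#' Computes the usage tables (per D gene, per J gene, per J cluster, per C
#' isotype, plus within-cluster J gene shares) and, via [classify_events()],
#' the rearrangement- and splice-class censuses. D usage and rearrangement
#' classes are tabulated under both denominators: all clones and D-assigned
#' clones.
#'
#' @param records clone table with columns `d_gene`/`j_gene`/`c_gene` (or
#'   `d_call`/`j_call`/`c_call`) and `cdr3_len_aa` or `cdr3_length_aa`.
#' @param locus a `trb_locus` giving the cluster topology.
#' @return list of data.frames: `totals`, `d_usage`, `d_usage_all`,
#'   `j_usage`, `j_cluster_usage`, `j_within_cluster`, `c_usage`,
#'   `rearrangement` (both denominators), `splice`.
#' @export
summarize_repertoire <- function(records, locus) {
  dg <- records$d_gene %||% records$d_call
  jg <- records$j_gene %||% records$j_call
  cg <- records$c_gene %||% records$c_call
  dg[is.na(dg) | dg == ""] <- "none"
  n_all <- nrow(records)
  if (n_all == 0L) stop("no records to summarize", call. = FALSE)
  d_assigned <- dg != "none"
  n_d <- sum(d_assigned)

  d_levels <- locus$clusters$d_gene[order(locus$clusters$genomic_rank)]
  c_levels <- locus$clusters$c_gene[order(locus$clusters$genomic_rank)]
  cl_levels <- locus$clusters$cluster_id[order(locus$clusters$genomic_rank)]

  jcl <- cluster_of(locus, jg)
  j_cluster_usage <- count_pct(jcl, cl_levels, n_all)
  j_usage <- count_pct(jg, unlist(locus$j_genes[cl_levels],
                                  use.names = FALSE), n_all)
  j_within <- do.call(rbind, lapply(cl_levels, function(cid) {
    members <- locus$j_genes[[cid]]
    denom <- sum(jcl == cid)
    if (denom == 0L) return(NULL)
    out <- count_pct(jg[jcl == cid], members, denom)
    out$cluster_id <- cid
    out
  }))

  records2 <- data.frame(d_gene = dg, j_gene = jg, c_gene = cg,
                         stringsAsFactors = FALSE)
  ev <- classify_events(records2, locus)

  list(
    totals = data.frame(all_clones = n_all, d_assigned = n_d),
    d_usage = count_pct(dg[d_assigned], d_levels, n_d),
    d_usage_all = count_pct(dg, c(d_levels, "none"), n_all),
    j_usage = j_usage,
    j_cluster_usage = j_cluster_usage,
    j_within_cluster = j_within,
    c_usage = count_pct(cg, c_levels, n_all),
    rearrangement = count_pct(
      ev$rearrangement_class[d_assigned],
      c("intra_cluster", "inter_cluster", "trans_rearrangement"), n_d),
    rearrangement_all = count_pct(
      ev$rearrangement_class,
      c("intra_cluster", "inter_cluster", "trans_rearrangement", "no_d"),
      n_all),
    splice = count_pct(ev$splice_class,
                       c("canonical", "cis_splice", "trans_splice"), n_all)
  )
}

#' CDR3 length statistics per group
#'
#' Arithmetic mean (raw and truncated to one decimal) and min-max range of
#' the CDR3 length, grouped by tissue or by D group (the D gene, with
#' unassigned clones as `no_D`), in amino acids or nucleotides
#' (nt = 3 x aa). Empty groups are omitted with a message.
#'
#' @param records clone table (see [summarize_repertoire()]); needs
#'   `cdr3_len_aa` or `cdr3_length_aa`, `tissue` and/or a D column.
#' @param group_by `"tissue"` or `"d_group"`.
#' @param unit `"aa"` or `"nt"`.
#' @return data.frame with `group`, `n`, `mean` (truncated, 1 decimal),
#'   `mean_raw`, `min`, `max`.
#' @export
cdr3_stats <- function(records, group_by = c("tissue", "d_group"),
                       unit = c("aa", "nt")) {
  group_by <- match.arg(group_by)
  unit <- match.arg(unit)
  len <- records$cdr3_len_aa %||% records$cdr3_length_aa
  if (is.null(len)) stop("no CDR3 length column", call. = FALSE)
  if (unit == "nt") len <- 3L * len
  g <- if (group_by == "tissue") records$tissue else {
    dg <- records$d_gene %||% records$d_call
    dg[is.na(dg) | dg == ""] <- "none"
    ifelse(dg == "none", "no_D", dg)
  }
  keep <- !is.na(len) & !is.na(g)
  if (any(!keep)) message(sum(!keep), " record(s) without length omitted")
  len <- len[keep]; g <- g[keep]
  out <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
    x <- len[g == lev]
    data.frame(group = lev, n = length(x),
               mean = trunc1(mean(x)), mean_raw = mean(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
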