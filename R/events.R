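# Topology-based classification of rearrangement and splicing events.
#
# With the genomic order of the D-J-C clusters known, every D-J joining and
# every J-C pairing has a forced interpretation: same cluster is the
# ordinary (intra-cluster / canonical) case; a J downstream of its D is a
# deletional inter-cluster joining, while a J upstream of its D can only
# arise by chromosomal inversion or trans-rearrangement; a C downstream of
# the J cluster can be reached by alternative cis-splicing of one precursor
# RNA, while a C upstream of the J cluster requires trans-splicing of two
# separate precursors.

#' Classify a D-J rearrangement by cluster topology
#'
#' @param d_cluster cluster of the D gene (`NA` for clones without a
#'   recognizable D).
#' @param j_cluster cluster of the J gene.
#' @param locus a `trb_locus`.
#' @return `"no_d"`, `"intra_cluster"`, `"inter_cluster"` or
#'   `"trans_rearrangement"` (the latter covers both chromosomal inversion
#'   and inter-chromatid trans-rearrangement, which cDNA cannot separate).
#' @export
classify_rearrangement <- function(d_cluster, j_cluster, locus) {
  if (is.na(d_cluster)) return("no_d")
  if (d_cluster == j_cluster) {
    cluster_rank(locus, d_cluster)  # validate the id
    return("intra_cluster")
  }
  if (upstream_of(locus, d_cluster, j_cluster)) "inter_cluster"
  else "trans_rearrangement"
}

#' Classify a J-C pairing by cluster topology
#'
#' @param j_cluster cluster of the J gene.
#' @param c_cluster cluster of the C isotype.
#' @param locus a `trb_locus`.
#' @return `"canonical"`, `"cis_splice"` or `"trans_splice"`.
#' @export
classify_splice <- function(j_cluster, c_cluster, locus) {
  if (j_cluster == c_cluster) {
    cluster_rank(locus, j_cluster)
    return("canonical")
  }
  if (upstream_of(locus, j_cluster, c_cluster)) "cis_splice"
  else "trans_splice"
}

#' Append event classes to an annotated clone table
#'
#' Maps each record's D, J and C genes to their clusters and classifies the
#' rearrangement topology and the splice mode. Accepts either an annotation
#' table from [annotate_transcripts()] (columns `d_call`, `j_call`,
#' `c_call`) or a clone table with columns `d_gene`, `j_gene`, `c_gene`.
#'
#' @param records data.frame of annotated clones.
#' @param locus a `trb_locus`.
#' @return `records` with `rearrangement_class` and `splice_class` columns
#'   appended (NA where the genes are missing or uncallable).
#' @export
classify_events <- function(records, locus) {
  dg <- records$d_call %||% records$d_gene
  jg <- records$j_call %||% records$j_gene
  cg <- records$c_call %||% records$c_gene
  n <- nrow(records)
  rearr <- character(n); splice <- character(n)
  for (i in seq_len(n)) {
    if (is.na(jg[i])) { rearr[i] <- NA; splice[i] <- NA; next }
    jc <- cluster_of(locus, jg[i])
    dc <- if (is.na(dg[i]) || dg[i] %in% c("none", ""))
      NA_character_ else cluster_of(locus, dg[i])
    rearr[i] <- classify_rearrangement(dc, jc, locus)
    splice[i] <- if (is.na(cg[i])) NA_character_ else
      classify_splice(jc, cluster_of(locus, cg[i]), locus)
  }
  records$rearrangement_class <- rearr
  records$splice_class <- splice
  records
}
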