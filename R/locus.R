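# Germline model of a multi-cluster TRB D-J-C locus.
#
# A locus object holds the gene census (one D, an ordered J set and one C per
# cluster), the genomic order of the clusters, the constant-region exon
# partition, the marker table describing the variable constant-region
# positions with per-allele bases, and the junction anchoring information
# (conserved V-cysteine motif, J-gene FGXG phenylalanine offsets).

#' Construct a TRB locus model
#'
#' Builds and validates the germline model that every classifier consults.
#' Coordinates are 1-based inclusive in all user-facing fields; marker
#' positions are offsets from the first nucleotide of the constant-region
#' portion of the spliced cDNA.
#'
#' @param clusters data.frame with columns `cluster_id`, `genomic_rank`
#'   (1-based 5'-to-3' order along the chromosome), `d_gene`, `c_gene`.
#' @param j_genes named list mapping `cluster_id` to the ordered character
#'   vector of J gene names in that cluster.
#' @param seqs named character vector of germline nucleotide sequences for
#'   every D, J and C gene (C genes as the spliced cDNA constant portion).
#' @param kinds named character vector mapping gene name to one of
#'   `"D"`, `"J"`, `"C"`.
#' @param functional named logical vector per gene (default all `TRUE`).
#' @param c_exons data.frame with columns `exon`, `start`, `end`: the exon
#'   partition of the constant-region cDNA portion.
#' @param j_phe named integer vector: for each J gene, the 1-based offset of
#'   the first nucleotide of the FGXG phenylalanine codon within the germline
#'   J sequence.
#' @param markers data.frame with columns `idx`, `region` (an exon label) and
#'   `position` (1-based offset in the constant cDNA portion).
#' @param allele_bases character matrix, rows = markers (in `idx` order),
#'   columns = allele names, entries the allele's base at that marker.
#' @param allele_isotype named character vector mapping allele name to its C
#'   gene (at most two alleles per isotype).
#' @param diagnostics integer vector of marker indices jointly sufficient to
#'   call the C isotype from the N-terminus.
#' @param anchor list with `motif` (amino-acid anchor, default `"YLCASS"`),
#'   `cys_index` (position of the conserved cysteine within the motif) and
#'   `nt` (nucleotide sequence of the anchor region used by the simulator).
#' @param v_ends optional character vector of known germline V-end suffixes
#'   (the nucleotides that may follow the anchor), used for V-retained
#'   inference.
#' @param species,provenance free-text labels.
#' @return An object of class `trb_locus`.
#' @export
trb_locus <- function(clusters, j_genes, seqs, kinds, functional = NULL,
                      c_exons, j_phe, markers, allele_bases, allele_isotype,
                      diagnostics, anchor = NULL, v_ends = character(),
                      species = "unspecified", provenance = "unspecified") {
  if (is.null(functional))
    functional <- stats::setNames(rep(TRUE, length(seqs)), names(seqs))
  anchor <- anchor %||% list(motif = "YLCASS", cys_index = 3L,
                             nt = "TATCTCTGTGCCAGCAGC")
  genes <- data.frame(
    name = names(seqs),
    kind = unname(kinds[names(seqs)]),
    cluster_id = NA_character_,
    functional = unname(functional[names(seqs)]),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(clusters))) {
    cid <- clusters$cluster_id[i]
    members <- c(clusters$d_gene[i], j_genes[[cid]], clusters$c_gene[i])
    genes$cluster_id[match(members, genes$name)] <- cid
  }
  obj <- structure(
    list(species = species, provenance = provenance,
         genes = genes, seqs = seqs,
         clusters = clusters[order(clusters$genomic_rank), , drop = FALSE],
         j_genes = j_genes, c_exons = c_exons, j_phe = j_phe,
         markers = markers, allele_bases = allele_bases,
         allele_isotype = allele_isotype, diagnostics = as.integer(diagnostics),
         anchor = anchor, v_ends = v_ends),
    class = "trb_locus")
  validate_locus(obj)
  obj
}

#' Validate a locus model
#'
#' Checks every structural invariant: unique gene names over the DNA
#' alphabet, D genes of length >= 4, exactly one D and one C per cluster,
#' genomic ranks forming a permutation of 1..n, every J in exactly one
#' cluster, an exon partition with at least one exon covering all marker
#' positions, strictly increasing marker positions with >= 2 states each,
#' isotype diagnostics that jointly distinguish all isotypes, at most two
#' alleles per isotype, and a usable anchor/FGXG annotation.
#'
#' @param locus a `trb_locus`.
#' @return `locus`, invisibly; errors describe the first violated invariant.
#' @export
validate_locus <- function(locus) {
  g <- locus$genes
  if (anyDuplicated(g$name))
    stop("duplicate gene name: ", g$name[duplicated(g$name)][1L], call. = FALSE)
  if (any(is.na(g$kind)) || !all(g$kind %in% c("D", "J", "C")))
    stop("every gene must have kind D, J or C", call. = FALSE)
  for (nm in g$name) check_dna(locus$seqs[[nm]], paste0("sequence of ", nm))
  for (nm in g$name[g$kind == "D"])
    if (nchar(locus$seqs[[nm]]) < 4L)
      stop("D gene ", nm, " shorter than 4 nt", call. = FALSE)

  cl <- locus$clusters
  if (anyDuplicated(cl$cluster_id)) stop("duplicate cluster_id", call. = FALSE)
  if (!setequal(cl$genomic_rank, seq_len(nrow(cl))))
    stop("genomic_rank values must be a permutation of 1..n_clusters",
         call. = FALSE)
  for (i in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[i]
    for (col in c("d_gene", "c_gene")) {
      nm <- cl[[col]][i]
      if (!nm %in% g$name)
        stop("cluster ", cid, " names missing gene ", nm, call. = FALSE)
    }
    if (g$kind[match(cl$d_gene[i], g$name)] != "D")
      stop(cl$d_gene[i], " is not a D gene", call. = FALSE)
    if (g$kind[match(cl$c_gene[i], g$name)] != "C")
      stop(cl$c_gene[i], " is not a C gene", call. = FALSE)
    js <- locus$j_genes[[cid]]
    if (is.null(js) || length(js) < 1L)
      stop("cluster ", cid, " has no J genes", call. = FALSE)
    missing <- setdiff(js, g$name)
    if (length(missing))
      stop("cluster ", cid, " names missing gene ", missing[1L], call. = FALSE)
    if (!all(g$kind[match(js, g$name)] == "J"))
      stop("cluster ", cid, " lists a non-J gene in its J set", call. = FALSE)
  }
  all_j <- unlist(locus$j_genes, use.names = FALSE)
  if (anyDuplicated(all_j))
    stop("J gene assigned to more than one cluster: ",
         all_j[duplicated(all_j)][1L], call. = FALSE)
  if (!setequal(all_j, g$name[g$kind == "J"]))
    stop("every J gene must belong to exactly one cluster", call. = FALSE)

  # J anchoring: each J carries the offset of its FGXG phenylalanine codon.
  for (nm in all_j) {
    phe <- locus$j_phe[[nm]]
    if (is.null(phe) || is.na(phe))
      stop("missing FGXG phenylalanine offset for ", nm, call. = FALSE)
    jlen <- nchar(locus$seqs[[nm]])
    if (phe < 1L || phe + 11L > jlen)
      stop("FGXG motif of ", nm, " does not fit its sequence", call. = FALSE)
    aa <- translate_nt(substr(locus$seqs[[nm]], phe, phe + 11L))
    if (substr(aa, 1L, 1L) != "F" || substr(aa, 2L, 2L) != "G" ||
        substr(aa, 4L, 4L) != "G")
      stop("no FGXG motif at the stated offset of ", nm, call. = FALSE)
  }

  # Constant-region exon partition and markers.
  ce <- locus$c_exons
  if (is.null(ce) || nrow(ce) < 1L)
    stop("constant-region exon partition must have at least one exon",
         call. = FALSE)
  if (any(ce$start > ce$end)) stop("malformed exon partition", call. = FALSE)
  c_len <- max(ce$end)
  for (nm in g$name[g$kind == "C"])
    if (nchar(locus$seqs[[nm]]) < c_len)
      stop("C gene ", nm, " shorter than its exon partition", call. = FALSE)

  mk <- locus$markers
  if (nrow(mk) > 0L) {
    if (is.unsorted(mk$position, strictly = TRUE))
      stop("marker positions must be strictly increasing", call. = FALSE)
    if (!all(mk$region %in% ce$exon))
      stop("marker region not in the exon partition", call. = FALSE)
    for (i in seq_len(nrow(mk))) {
      e <- ce[ce$exon == mk$region[i], ]
      if (mk$position[i] < e$start || mk$position[i] > e$end)
        stop("marker ", mk$idx[i], " lies outside its exon", call. = FALSE)
    }
    ab <- locus$allele_bases
    if (nrow(ab) != nrow(mk))
      stop("allele_bases rows must match the marker table", call. = FALSE)
    if (any(apply(ab, 1L, function(r) length(unique(r))) < 2L))
      stop("every marker must have at least two distinct states", call. = FALSE)
    iso <- locus$allele_isotype
    if (!setequal(names(iso), colnames(ab)))
      stop("allele_isotype must name every allele column", call. = FALSE)
    if (any(table(iso) > 2L))
      stop("at most two alleles per isotype", call. = FALSE)
    if (!all(unique(iso) %in% g$name[g$kind == "C"]))
      stop("allele isotypes must be C genes of the locus", call. = FALSE)
    dg <- locus$diagnostics
    if (length(dg) < 1L || !all(dg %in% mk$idx))
      stop("isotype diagnostics must reference marker indices", call. = FALSE)
    # Diagnostics must be constant within an isotype and jointly distinguish
    # all isotypes present in the locus.
    dvec <- vapply(unique(iso), function(ct) {
      cols <- names(iso)[iso == ct]
      per <- apply(ab[match(dg, mk$idx), cols, drop = FALSE], 1L, unique)
      if (is.list(per) || (is.matrix(per) && nrow(per) > 1L))
        stop("diagnostic marker varies within isotype ", ct, call. = FALSE)
      paste(per, collapse = "")
    }, character(1))
    if (anyDuplicated(dvec))
      stop("isotype diagnostics do not distinguish all isotypes", call. = FALSE)
  }

  # Anchor.
  a <- locus$anchor
  if (sum(chars(a$motif) == "C") != 1L ||
      substr(a$motif, a$cys_index, a$cys_index) != "C")
    stop("anchor motif must contain exactly one designated cysteine",
         call. = FALSE)
  if (translate_nt(a$nt) != a$motif)
    stop("anchor nucleotide sequence does not encode the motif", call. = FALSE)
  invisible(locus)
}

#' @export
print.trb_locus <- function(x, ...) {
  cat("TRB locus model (", x$species, ")\n", sep = "")
  cat("  clusters (genomic order):",
      paste(x$clusters$cluster_id, collapse = " < "), "\n")
  cat("  J census:",
      paste(sprintf("%s=%d", names(j_census(x)), j_census(x)), collapse = ", "),
      "\n")
  cat("  markers:", nrow(x$markers), "(",
      sum(x$markers$region == x$markers$region[1L]), "in", x$markers$region[1L],
      ")\n")
  invisible(x)
}

#' Genomic order of two clusters
#'
#' `TRUE` iff cluster `a` lies strictly upstream (5') of cluster `b`. The
#' relation is a strict total order over the clusters, consistent with the
#' layout's `genomic_rank`.
#'
#' @param locus a `trb_locus`.
#' @param a,b cluster ids.
#' @export
upstream_of <- function(locus, a, b) {
  r <- cluster_rank(locus, c(a, b))
  r[1L] < r[2L]
}

# Rank lookup with error on unknown ids.
cluster_rank <- function(locus, ids) {
  m <- match(ids, locus$clusters$cluster_id)
  if (anyNA(m))
    stop("unknown cluster id: ", ids[is.na(m)][1L], call. = FALSE)
  locus$clusters$genomic_rank[m]
}

#' Cluster membership of a gene
#' @param locus a `trb_locus`.
#' @param gene gene name(s).
#' @return cluster id(s).
#' @export
cluster_of <- function(locus, gene) {
  m <- match(gene, locus$genes$name)
  if (anyNA(m)) stop("unknown gene: ", gene[is.na(m)][1L], call. = FALSE)
  locus$genes$cluster_id[m]
}

#' J gene census per cluster
#' @param locus a `trb_locus`.
#' @return named integer vector, cluster id -> number of J genes.
#' @export
j_census <- function(locus) {
  vapply(locus$j_genes, length, integer(1))[locus$clusters$cluster_id]
}

#' Write a locus model to a layout file and germline FASTA
#'
#' The layout is YAML (clusters, genomic ranks, exon partition, FGXG offsets,
#' marker table with per-allele bases, diagnostics, anchor, V-end suffixes);
#' the FASTA holds one record per gene with `kind=` / `cluster=` /
#' `functional=` tokens in the description. `load_locus()` inverts this
#' exactly.
#'
#' @param locus a `trb_locus`.
#' @param layout_path,fasta_path output paths.
#' @return the two paths, invisibly.
#' @export
write_locus <- function(locus, layout_path, fasta_path) {
  mk <- locus$markers
  layout <- list(
    species = locus$species,
    provenance = locus$provenance,
    clusters = lapply(seq_len(nrow(locus$clusters)), function(i) {
      cid <- locus$clusters$cluster_id[i]
      list(cluster_id = cid,
           genomic_rank = locus$clusters$genomic_rank[i],
           d_gene = locus$clusters$d_gene[i],
           j_genes = as.list(locus$j_genes[[cid]]),
           c_gene = locus$clusters$c_gene[i])
    }),
    c_exons = lapply(seq_len(nrow(locus$c_exons)), function(i)
      list(exon = locus$c_exons$exon[i],
           start = locus$c_exons$start[i], end = locus$c_exons$end[i])),
    j_phe = as.list(locus$j_phe),
    markers = lapply(seq_len(nrow(mk)), function(i)
      list(idx = mk$idx[i], region = mk$region[i], position = mk$position[i],
           alleles = as.list(locus$allele_bases[i, ]))),
    isotype_diagnostics = as.list(locus$diagnostics),
    alleles = as.list(locus$allele_isotype),
    anchor = locus$anchor,
    v_ends = as.list(locus$v_ends)
  )
  yaml::write_yaml(layout, layout_path)
  g <- locus$genes
  dna <- Biostrings::DNAStringSet(unlist(locus$seqs[g$name]))
  names(dna) <- sprintf("%s kind=%s cluster=%s functional=%s",
                        g$name, g$kind, g$cluster_id, g$functional)
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(c(layout = layout_path, fasta = fasta_path))
}

#' Load a locus model from a layout file and germline FASTA
#'
#' @param layout_path YAML layout written by [write_locus()] (or authored by
#'   hand in the same dialect).
#' @param fasta_path germline FASTA; description tokens `kind=`, `cluster=`
#'   and `functional=` annotate each gene.
#' @return a validated `trb_locus`.
#' @export
load_locus <- function(layout_path, fasta_path) {
  layout <- yaml::read_yaml(layout_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  full <- names(dna)
  gene_names <- sub("\\s.*$", "", full)
  tok <- function(key) {
    m <- regmatches(full, regexpr(paste0(key, "=[^ ]+"), full))
    vals <- rep(NA_character_, length(full))
    hit <- grepl(paste0(key, "="), full)
    vals[hit] <- sub(paste0("^", key, "="), "", m)
    vals
  }
  kinds <- stats::setNames(tok("kind"), gene_names)
  functional <- stats::setNames(tok("functional") == "TRUE", gene_names)
  seqs <- stats::setNames(as.character(dna), gene_names)

  cl <- do.call(rbind, lapply(layout$clusters, function(x)
    data.frame(cluster_id = x$cluster_id, genomic_rank = x$genomic_rank,
               d_gene = x$d_gene, c_gene = x$c_gene,
               stringsAsFactors = FALSE)))
  j_genes <- stats::setNames(
    lapply(layout$clusters, function(x) unlist(x$j_genes)),
    vapply(layout$clusters, `[[`, character(1), "cluster_id"))
  named <- unique(c(cl$d_gene, cl$c_gene, unlist(j_genes)))
  missing <- setdiff(named, gene_names)
  if (length(missing))
    stop("layout names gene absent from FASTA: ", missing[1L], call. = FALSE)

  mk <- do.call(rbind, lapply(layout$markers, function(x)
    data.frame(idx = x$idx, region = x$region, position = x$position,
               stringsAsFactors = FALSE)))
  if (is.null(mk)) mk <- data.frame(idx = integer(), region = character(),
                                    position = integer())
  allele_names <- if (length(layout$markers))
    names(layout$markers[[1L]]$alleles) else character()
  ab <- matrix(NA_character_, nrow = nrow(mk), ncol = length(allele_names),
               dimnames = list(NULL, allele_names))
  for (i in seq_along(layout$markers))
    ab[i, ] <- unlist(layout$markers[[i]]$alleles[allele_names])

  trb_locus(
    clusters = cl, j_genes = j_genes, seqs = seqs, kinds = kinds,
    functional = functional,
    c_exons = do.call(rbind, lapply(layout$c_exons, function(x)
      data.frame(exon = x$exon, start = x$start, end = x$end,
                 stringsAsFactors = FALSE))),
    j_phe = stats::setNames(as.integer(unlist(layout$j_phe)),
                            names(layout$j_phe)),
    markers = mk, allele_bases = ab,
    allele_isotype = stats::setNames(unlist(layout$alleles),
                                     names(layout$alleles)),
    diagnostics = unlist(layout$isotype_diagnostics),
    anchor = list(motif = layout$anchor$motif,
                  cys_index = as.integer(layout$anchor$cys_index),
                  nt = layout$anchor$nt),
    v_ends = as.character(unlist(layout$v_ends) %||% character()),
    species = layout$species %||% "unspecified",
    provenance = layout$provenance %||% "unspecified"
  )
}
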