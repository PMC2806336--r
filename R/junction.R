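# CDR3 extraction and junction decomposition.
#
# Each transcript is anchored on the conserved V-gene cysteine motif
# (YLCASS by default; the cysteine is position 104 of the V gene), its
# constant portion is located from the germline C sequences, the J gene is
# the germline J whose suffix matches the transcript exactly after 5'
# trimming, and the CDR3 runs from the codon after the anchor cysteine up to
# (exclusive) the codon of the J-gene FGXG phenylalanine. The junction is
# then decomposed into V-retained / N1 / D (with trims and substitutions) /
# N2 / J-retained parts that reconstruct the observed junction exactly.

# ---- anchoring ------------------------------------------------------------

# Find the anchor motif across the three reading frames. Returns the 1-based
# nt position of the last nucleotide of the anchor cysteine codon. Errors on
# absent or ambiguous anchors.
locate_anchor <- function(seq, anchor) {
  hits <- integer()
  n <- nchar(seq)
  for (f in 0:2) {
    m <- n - f
    if (m < 3L) next
    aa <- translate_nt(substr(seq, f + 1L, f + 3L * (m %/% 3L)))
    p <- gregexpr(anchor$motif, aa, fixed = TRUE)[[1L]]
    if (p[1L] > 0L)
      hits <- c(hits, f + (p - 1L) * 3L + anchor$cys_index * 3L)
  }
  if (length(hits) == 0L) stop("anchor motif not found", call. = FALSE)
  if (length(hits) > 1L) stop("anchor motif is ambiguous (multiple in-frame hits)",
                              call. = FALSE)
  hits
}

# ---- constant-region location --------------------------------------------

# Marker-free probes per C gene: longest marker-free stretch of each C cDNA,
# used to pin the start of the constant portion in a transcript.
c_probes <- function(locus) {
  c_names <- locus$genes$name[locus$genes$kind == "C"]
  probes <- lapply(c_names, function(nm) {
    len <- nchar(locus$seqs[[nm]])
    mask <- rep(FALSE, len)
    mask[locus$markers$position] <- TRUE
    r <- rle(!mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    free <- which(r$values)
    best <- free[which.max(r$lengths[free])]
    if (r$lengths[best] < 12L)
      stop("no usable marker-free stretch in ", nm, call. = FALSE)
    list(c_gene = nm,
         probe = substr(locus$seqs[[nm]], starts[best], ends[best]),
         offset = starts[best] - 1L)
  })
  probes[!duplicated(vapply(probes, `[[`, character(1), "probe"))]
}

# Locate the constant portion: returns the transcript position of the first
# C nucleotide, validating that the observed region matches the germline C
# except possibly at marker positions.
locate_c_start <- function(seq, locus, probes) {
  for (pr in probes) {
    at <- regexpr(pr$probe, seq, fixed = TRUE)
    if (at < 1L) next
    c_start <- as.integer(at) - pr$offset
    if (c_start < 2L) next
    ref <- locus$seqs[[pr$c_gene]]
    obs_len <- min(nchar(ref), nchar(seq) - c_start + 1L)
    obs <- substr(seq, c_start, c_start + obs_len - 1L)
    mism <- which(utf8ToInt(obs) != utf8ToInt(substr(ref, 1L, obs_len)))
    if (all(mism %in% locus$markers$position)) return(c_start)
  }
  stop("constant region not found", call. = FALSE)
}

#' Call the constant-gene isotype from diagnostic marker positions
#'
#' Reads the bases of the observed constant portion at the locus'
#' isotype-diagnostic marker positions and reports the unique isotype whose
#' diagnostic bases all match. Ambiguity is reported explicitly, never
#' resolved to a default.
#'
#' @param c_nt observed constant portion (from its first nucleotide).
#' @param locus a `trb_locus`.
#' @return list with `c_gene` (name or `NA`) and `status`: `"ok"`,
#'   `"ambiguous"` (several isotypes match) or `"novel"` (none matches).
#'   A constant portion not covering all diagnostic positions is an error
#'   (truncated constant region).
#' @export
call_c_isotype <- function(c_nt, locus) {
  dg <- locus$diagnostics
  if (length(dg) == 0L) {
    iso <- unique(c(locus$allele_isotype,
                    locus$genes$name[locus$genes$kind == "C"]))
    return(if (length(iso) == 1L) list(c_gene = iso, status = "ok")
           else list(c_gene = NA_character_, status = "ambiguous"))
  }
  pos <- locus$markers$position[match(dg, locus$markers$idx)]
  if (nchar(c_nt) < max(pos))
    stop("constant portion truncated before diagnostic positions",
         call. = FALSE)
  obs <- substring(c_nt, pos, pos)
  iso <- unique(locus$allele_isotype)
  hit <- vapply(iso, function(ct) {
    al <- names(locus$allele_isotype)[locus$allele_isotype == ct][1L]
    all(locus$allele_bases[match(dg, locus$markers$idx), al] == obs)
  }, logical(1))
  if (sum(hit) == 1L) list(c_gene = iso[hit], status = "ok")
  else if (sum(hit) > 1L) list(c_gene = NA_character_, status = "ambiguous")
  else list(c_gene = NA_character_, status = "novel")
}

# ---- CDR3 extraction ------------------------------------------------------

#' Extract the CDR3 and assign the J gene
#'
#' The CDR3 runs from the codon after the anchor cysteine up to (exclusive)
#' the codon of the J-gene FGXG phenylalanine. The J gene is the germline J
#' whose suffix (after 5' trimming) matches the transcript exactly, found by
#' maximising the exact suffix match ending where the constant portion
#' begins; a minimum match length guards against spurious calls.
#'
#' @param transcript nucleotide string.
#' @param locus a `trb_locus`.
#' @param min_j_match minimum exact J suffix match in nt (default 6, two
#'   codons).
#' @param probes precomputed constant-region probes (internal; defaults to
#'   computing them from the locus).
#' @return list with `cdr3_nt`, `cdr3_aa` (`NA` when out of frame),
#'   `productive` (in frame and stop-free), `j_gene`, `j_trim`, `c_start`,
#'   `c_call` (from [call_c_isotype()]), and `anchor_end`.
#' @export
extract_cdr3 <- function(transcript, locus, min_j_match = 6L,
                         probes = c_probes(locus)) {
  check_dna(transcript, "transcript")
  ce <- locate_anchor(transcript, locus$anchor)
  c_start <- locate_c_start(transcript, locus, probes)
  if (c_start <= ce) stop("constant region precedes the anchor", call. = FALSE)
  region <- substr(transcript, ce + 1L, c_start - 1L)

  jn <- unlist(locus$j_genes, use.names = FALSE)
  k <- vapply(jn, function(nm) common_suffix_len(region, locus$seqs[[nm]]),
              integer(1))
  k_best <- max(k)
  if (k_best < min_j_match)
    stop("no germline J suffix match of at least ", min_j_match, " nt",
         call. = FALSE)
  tied <- jn[k == k_best]
  if (length(tied) > 1L)
    stop("ambiguous J assignment: ", paste(tied, collapse = ", "),
         call. = FALSE)
  j_gene <- tied
  j_len <- nchar(locus$seqs[[j_gene]])
  j_trim <- j_len - k_best
  phe <- locus$j_phe[[j_gene]]
  if (j_trim >= phe)
    stop("J 5' trimming removed the FGXG phenylalanine of ", j_gene,
         call. = FALSE)
  t_phe <- c_start - 1L - (j_len - phe)  # F codon start in the transcript
  cdr3_nt <- substr(transcript, ce + 1L, t_phe - 1L)
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- if (in_frame) translate_nt(cdr3_nt) else NA_character_
  productive <- in_frame && !grepl("*", cdr3_aa, fixed = TRUE)
  c_nt <- substr(transcript, c_start, nchar(transcript))
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive,
       j_gene = j_gene, j_trim = j_trim, c_start = c_start,
       c_call = call_c_isotype(c_nt, locus), c_nt = c_nt, anchor_end = ce)
}

#' CDR3 length in amino acids
#'
#' Counts the amino acids between the residue after the conserved V
#' cysteine and the residue before the FGXG phenylalanine (this convention
#' yields three amino acids more than the Kabat delimitation).
#'
#' @param annotation a junction annotation (or any list with `cdr3_nt`).
#' @return integer amino-acid length; error if the CDR3 is out of frame.
#' @export
cdr3_length <- function(annotation) {
  nt <- annotation$cdr3_nt %||% annotation$junction
  if (nchar(nt) %% 3L != 0L)
    stop("CDR3 is out of frame (", nchar(nt), " nt)", call. = FALSE)
  nchar(nt) %/% 3L
}

# ---- D assignment ---------------------------------------------------------

# Longest exact run shared between `central` and germline D `d_seq`, at
# least min_run long. Returns NULL or list(len, s (central), gs (germline)),
# preferring longer runs, then 5'-most germline, then 5'-most central.
longest_d_run <- function(central, d_seq, min_run) {
  lc <- nchar(central); ld <- nchar(d_seq)
  if (min(lc, ld) < min_run) return(NULL)
  for (L in seq(min(lc, ld), min_run)) {
    starts <- seq_len(ld - L + 1L)
    for (gs in starts) {
      at <- regexpr(substr(d_seq, gs, gs + L - 1L), central, fixed = TRUE)
      if (at > 0L) return(list(len = L, s = as.integer(at), gs = gs))
    }
  }
  NULL
}

#' Assign the D gene within a junction
#'
#' Applies the minimum-run rule: the unexplained central region of the
#' junction (after the V-retained prefix, before the J-retained suffix) is
#' scanned for the longest stretch of consecutive nucleotides matching each
#' germline D; the D with the longest run of at least `min_run` nt (default
#' 4) is called. Optionally the exact seed is extended outward, accepting
#' isolated substitutions flanked by matching bases; every deviation is
#' recorded, never silently absorbed. Equal-length runs for several D genes
#' are a tie: under policy `"none"` no gene is called and the candidates are
#' reported; under `"priority"` the tie is broken by genomic order of the D
#' clusters.
#'
#' @param junction_nt the junction (CDR3) nucleotide string.
#' @param v_retained_len length of the junction prefix attributed to V.
#' @param j_start 1-based position in the junction where the J-retained part
#'   begins (`nchar(junction_nt) + 1` if none).
#' @param locus a `trb_locus`.
#' @param min_run minimum exact run, in nucleotides.
#' @param tie_policy `"none"` or `"priority"`.
#' @param extend_subs extend the exact seed across isolated substitutions.
#' @return a D call: list with `gene` (name or `"none"`), `candidates`,
#'   `match_start`/`match_end` (junction coordinates), `g_start`/`g_end`
#'   (germline coordinates), `five_prime_trim`, `three_prime_trim`,
#'   `substitutions` (data.frame offset/ref/obs in germline coordinates) and
#'   `matched` (the observed matched segment).
#' @export
assign_d <- function(junction_nt, v_retained_len, j_start, locus,
                     min_run = 4L, tie_policy = c("none", "priority"),
                     extend_subs = TRUE) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(min_run >= 1L)
  central_start <- v_retained_len + 1L
  central <- substr(junction_nt, central_start, j_start - 1L)
  no_call <- list(gene = "none", candidates = character(),
                  match_start = NA_integer_, match_end = NA_integer_,
                  g_start = NA_integer_, g_end = NA_integer_,
                  five_prime_trim = NA_integer_, three_prime_trim = NA_integer_,
                  substitutions = data.frame(offset = integer(),
                                             ref = character(),
                                             obs = character()),
                  matched = "")
  if (nchar(central) < min_run) return(no_call)

  # D genes in genomic order of their clusters (the priority order).
  ord <- order(locus$clusters$genomic_rank)
  d_names <- locus$clusters$d_gene[ord]
  runs <- lapply(d_names, function(nm)
    longest_d_run(central, locus$seqs[[nm]], min_run))
  lens <- vapply(runs, function(r) if (is.null(r)) 0L else r$len, integer(1))
  if (max(lens) < min_run) return(no_call)
  tied <- d_names[lens == max(lens)]
  if (length(tied) > 1L && tie_policy == "none") {
    out <- no_call
    out$candidates <- tied
    return(out)
  }
  gene <- tied[1L]
  run <- runs[[match(gene, d_names)]]
  d_seq <- locus$seqs[[gene]]
  ld <- nchar(d_seq)
  s <- run$s; e <- run$s + run$len - 1L
  gs <- run$gs; ge <- run$gs + run$len - 1L
  subs <- list()

  if (extend_subs) {
    # Leftward: accept a substitution only when the preceding base matches
    # again (lookahead), so N regions are not absorbed.
    cc <- chars(central); dd <- chars(d_seq)
    repeat {
      if (s <= 1L || gs <= 1L) break
      if (cc[s - 1L] == dd[gs - 1L]) { s <- s - 1L; gs <- gs - 1L; next }
      if (s > 2L && gs > 2L && cc[s - 2L] == dd[gs - 2L]) {
        subs[[length(subs) + 1L]] <- data.frame(offset = gs - 1L,
                                                ref = dd[gs - 1L],
                                                obs = cc[s - 1L])
        s <- s - 2L; gs <- gs - 2L; next
      }
      break
    }
    repeat {
      if (e >= nchar(central) || ge >= ld) break
      if (cc[e + 1L] == dd[ge + 1L]) { e <- e + 1L; ge <- ge + 1L; next }
      if (e + 2L <= nchar(central) && ge + 2L <= ld &&
          cc[e + 2L] == dd[ge + 2L]) {
        subs[[length(subs) + 1L]] <- data.frame(offset = ge + 1L,
                                                ref = dd[ge + 1L],
                                                obs = cc[e + 1L])
        e <- e + 2L; ge <- ge + 2L; next
      }
      break
    }
  }
  subs <- if (length(subs)) {
    df <- do.call(rbind, subs)
    df[order(df$offset), , drop = FALSE]
  } else data.frame(offset = integer(), ref = character(), obs = character())
  list(gene = gene, candidates = tied,
       match_start = central_start + s - 1L,
       match_end = central_start + e - 1L,
       g_start = gs, g_end = ge,
       five_prime_trim = gs - 1L, three_prime_trim = ld - ge,
       substitutions = subs,
       matched = substr(central, s, e))
}

# ---- decomposition --------------------------------------------------------

# Greedy V-retained inference: the anchor tail (motif residues after the
# cysteine) is always V-origin; beyond it, the longest junction prefix
# matching a prefix of a supplied germline V-end suffix is attributed to V.
v_retained_length <- function(junction_nt, locus, v_ends, limit) {
  tail_len <- nchar(locus$anchor$nt) - locus$anchor$cys_index * 3L
  if (length(v_ends) == 0L) return(min(tail_len, limit))
  rest <- substr(junction_nt, tail_len + 1L, limit)
  extra <- if (nchar(rest) == 0L) 0L else
    max(vapply(v_ends, function(v) common_prefix_len(rest, v), integer(1)))
  min(tail_len + extra, limit)
}

#' Decompose a junction into V / N1 / D / N2 / J parts
#'
#' Splits the observed junction so that
#' `v_retained + n1 + d_observed + n2 + j_retained` reconstructs it exactly.
#' The V-retained prefix is the conserved anchor tail plus the longest match
#' against a supplied germline V-end suffix (greedy, longest wins; without a
#' V-end list only the anchor tail is attributed to V and N1 absorbs the
#' rest); N1 and N2 are the residues around the D match.
#'
#' @param cdr3_nt the junction nucleotide string.
#' @param d_call a D call from [assign_d()].
#' @param j_gene,j_trim the J assignment (see [extract_cdr3()]).
#' @param locus a `trb_locus`.
#' @param v_ends germline V-end suffixes; defaults to the locus' list.
#' @return a junction annotation: list with `v_retained`, `n1`, `d_call`,
#'   `n2`, `j_retained`, `j_gene`, `j_trim`, `cdr3_nt`, `cdr3_aa`,
#'   `cdr3_len_nt`, `cdr3_len_aa` (`NA` when out of frame).
#' @export
decompose_junction <- function(cdr3_nt, d_call, j_gene, j_trim, locus,
                               v_ends = locus$v_ends) {
  phe <- locus$j_phe[[j_gene]]
  j_in_len <- max(0L, phe - 1L - j_trim)
  len <- nchar(cdr3_nt)
  j_start <- len - j_in_len + 1L
  v_len <- v_retained_length(cdr3_nt, locus, v_ends, j_start - 1L)
  v_retained <- substr(cdr3_nt, 1L, v_len)
  j_retained <- substr(cdr3_nt, j_start, len)
  if (d_call$gene == "none") {
    n1 <- substr(cdr3_nt, v_len + 1L, j_start - 1L)
    n2 <- ""
  } else {
    n1 <- substr(cdr3_nt, v_len + 1L, d_call$match_start - 1L)
    n2 <- substr(cdr3_nt, d_call$match_end + 1L, j_start - 1L)
  }
  d_obs <- if (d_call$gene == "none") "" else d_call$matched
  recon <- paste0(v_retained, n1, d_obs, n2, j_retained)
  if (!identical(recon, cdr3_nt))
    stop("internal junction reconstruction failure", call. = FALSE)
  in_frame <- len %% 3L == 0L
  list(v_retained = v_retained, n1 = n1, d_call = d_call, n2 = n2,
       j_retained = j_retained, j_gene = j_gene, j_trim = j_trim,
       cdr3_nt = cdr3_nt,
       cdr3_aa = if (in_frame) translate_nt(cdr3_nt) else NA_character_,
       cdr3_len_nt = len,
       cdr3_len_aa = if (in_frame) len %/% 3L else NA_integer_)
}

# ---- repertoire annotation ------------------------------------------------

#' Annotate a set of transcripts
#'
#' Runs anchoring, constant-region location, J assignment, CDR3 extraction,
#' D assignment and junction decomposition on every transcript and returns a
#' rearrangement table in AIRR style (one row per input record; records that
#' fail carry their failure reason, never a silent drop).
#'
#' @param sequences named character vector of transcript sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param locus a `trb_locus`.
#' @param min_run minimum D run (nt) for [assign_d()].
#' @param min_j_match minimum J suffix match (nt).
#' @param tie_policy D tie policy, see [assign_d()].
#' @param extend_subs extend D seeds across isolated substitutions.
#' @param v_ends germline V-end suffixes for V-retained inference.
#' @return data.frame with columns `sequence_id`, `productive`,
#'   `v_retained`, `np1`, `d_call`, `d_candidates`, `d_5p_trim`,
#'   `d_3p_trim`, `d_observed`, `d_substitutions`, `np2`, `j_call`,
#'   `j_5p_trim`, `c_call`, `c_call_status`, `c_marker_vector`, `junction`,
#'   `junction_aa`, `junction_length`, `cdr3_length_aa`, `fail_reason`.
#' @export
annotate_transcripts <- function(sequences, locus, min_run = 4L,
                                 min_j_match = 6L,
                                 tie_policy = c("none", "priority"),
                                 extend_subs = TRUE,
                                 v_ends = locus$v_ends) {
  tie_policy <- match.arg(tie_policy)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(sequences) %||% sprintf("seq%05d", seq_along(sequences))
  if (is.null(names(sequences))) names(sequences) <- ids
  mk_pos <- locus$markers$position
  probes <- c_probes(locus)

  rows <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    id <- ids[i]
    row <- data.frame(
      sequence_id = id, productive = NA, v_retained = NA_character_,
      np1 = NA_character_, d_call = NA_character_, d_candidates = "",
      d_5p_trim = NA_integer_, d_3p_trim = NA_integer_,
      d_observed = NA_character_, d_substitutions = "",
      np2 = NA_character_, j_call = NA_character_, j_5p_trim = NA_integer_,
      c_call = NA_character_, c_call_status = NA_character_,
      c_marker_vector = NA_character_, junction = NA_character_,
      junction_aa = NA_character_, junction_length = NA_integer_,
      cdr3_length_aa = NA_integer_, fail_reason = NA_character_,
      stringsAsFactors = FALSE)
    res <- tryCatch({
      ext <- extract_cdr3(sequences[[i]], locus, min_j_match = min_j_match,
                          probes = probes)
      phe <- locus$j_phe[[ext$j_gene]]
      j_in_len <- max(0L, phe - 1L - ext$j_trim)
      len <- nchar(ext$cdr3_nt)
      v_len <- v_retained_length(ext$cdr3_nt, locus, v_ends,
                                 len - j_in_len)
      dc <- assign_d(ext$cdr3_nt, v_len, len - j_in_len + 1L, locus,
                     min_run = min_run, tie_policy = tie_policy,
                     extend_subs = extend_subs)
      dec <- decompose_junction(ext$cdr3_nt, dc, ext$j_gene, ext$j_trim,
                                locus, v_ends = v_ends)
      obs_mk <- ifelse(mk_pos <= nchar(ext$c_nt),
                       substring(ext$c_nt, mk_pos, mk_pos), "N")
      row$productive <- ext$productive
      row$v_retained <- dec$v_retained
      row$np1 <- dec$n1
      row$d_call <- dc$gene
      row$d_candidates <- paste(dc$candidates, collapse = ",")
      row$d_5p_trim <- dc$five_prime_trim
      row$d_3p_trim <- dc$three_prime_trim
      row$d_observed <- dc$matched
      row$d_substitutions <- if (nrow(dc$substitutions))
        paste(sprintf("%d:%s>%s", dc$substitutions$offset,
                      dc$substitutions$ref, dc$substitutions$obs),
              collapse = ",") else ""
      row$np2 <- dec$n2
      row$j_call <- ext$j_gene
      row$j_5p_trim <- ext$j_trim
      row$c_call <- ext$c_call$c_gene
      row$c_call_status <- ext$c_call$status
      row$c_marker_vector <- paste(obs_mk, collapse = "")
      row$junction <- ext$cdr3_nt
      row$junction_aa <- ext$cdr3_aa
      row$junction_length <- len
      row$cdr3_length_aa <- if (len %% 3L == 0L) len %/% 3L else NA_integer_
      row
    }, error = function(e) {
      row$fail_reason <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
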