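Package: trbrep
Title: T Cell Receptor Beta D-J-C Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of rearranged T cell receptor beta-chain (TRB) cDNA
    transcripts against a multi-cluster D-J-C germline locus, as found in
    ruminants where three tandem clusters (each one TRBD, an ordered TRBJ set
    and one TRBC gene) expand the beta-chain repertoire. Recovers CDR3
    junctions between the conserved V-gene cysteine (position 104) and the
    J-gene FGXG phenylalanine, assigns D genes by a minimum-run matching rule,
    decomposes junctions into V-retained, N-addition and trimmed D/J parts,
    classifies rearrangements by locus topology (intra-cluster, inter-cluster,
    trans-rearrangement) and J-to-C splicing (canonical, cis, trans), calls
    constant-region isotypes from diagnostic marker positions and explains
    observed constant-region marker vectors as alleles, exon-swap splice
    products or single-crossover recombinants. A seeded synthetic-repertoire
    generator with full per-transcript ground truth supports end-to-end
    validation, and summary functions reproduce gene-usage and CDR3-length
    statistics from annotated clone tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
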