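#!/usr/bin/env Rscript
# Constant-region variant analysis on a synthetic repertoire with elevated
# exon-swap and recombination rates: collects the marker-vector census per
# isotype and explains each vector as allele / exon-swap / single-crossover
# recombinant, mirroring how observed sequence groups in excess of the two
# expected allelic forms are resolved.

suppressPackageStartupMessages(library(trbrep))
dir.create("results", showWarnings = FALSE)

locus <- make_fixture_locus()
cfg <- sim_config(locus, exon_swap_rate = 0.15, recomb_rate = 0.15)
sim <- simulate_repertoire(cfg, 1000L, seed = 7L)
ann <- annotate_transcripts(sim$sequences, locus)
census <- explain_repertoire_variants(ann, locus)
write.table(census, "results/c_variant_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d distinct (isotype, marker-vector) groups over %d clones",
                nrow(census), sum(census$count)))
by_iso <- split(census, census$c_call)
for (iso in names(by_iso)) {
  g <- by_iso[[iso]]
  message(sprintf("%s: %d groups (%s)", iso, nrow(g),
                  paste(sprintf("%s x%d", g$class, g$count), collapse = ", ")))
  if (nrow(g) > 2L)
    message("  -> more groups than the expected two allelic forms; ",
            "the excess is explained by exon swaps / recombinants above")
}
# Recovery against the generator's truth labels.
tr <- sim$truth
cls <- vapply(ann$c_marker_vector, function(v)
  explain_variant(v, locus)$class, character(1))
acc <- mean(cls == tr$c_variant_class)
message(sprintf("Variant-class agreement with simulation truth: %.3f", acc))
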