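#!/usr/bin/env Rscript
# End-to-end validation of the annotation pipeline on a labelled synthetic
# repertoire drawn under the study regime (observed class mixtures
# 25:32:3 over D-assigned, 12/72 no-D, splices 49:7:16). Measures how well
# annotation recovers the generator's ground truth and writes the metrics.

suppressPackageStartupMessages(library(trbrep))
dir.create("results", showWarnings = FALSE)

locus <- make_fixture_locus()
cfg <- sim_config(locus)
n <- 2000L
sim <- simulate_repertoire(cfg, n, seed = 42L)
ann <- annotate_transcripts(sim$sequences, locus)
ann <- classify_events(ann, locus)
tr <- sim$truth

keep <- tr$d_gene != "none" & nchar(tr$d_observed) >= 6L
metrics <- data.frame(
  metric = c("n_transcripts", "annotation_failures",
             "junction_identity", "j_gene_recovery", "j_trim_recovery",
             "d_gene_recovery_retained6", "spurious_d_in_no_d",
             "c_isotype_recovery", "marker_vector_identity",
             "rearrangement_class_agreement", "splice_class_agreement"),
  value = c(n, sum(!is.na(ann$fail_reason)),
            mean(ann$junction == tr$junction),
            mean(ann$j_call == tr$j_gene),
            mean(ann$j_5p_trim == tr$j_5p_trim),
            mean(ann$d_call[keep] == tr$d_gene[keep]),
            mean(ann$d_call[tr$d_gene == "none"] != "none"),
            mean(ann$c_call == tr$c_gene),
            mean(ann$c_marker_vector == tr$c_marker_vector),
            mean(ann$rearrangement_class[keep] ==
                   tr$rearrangement_class[keep]),
            mean(ann$splice_class == tr$splice_class)))
write.table(metrics, "results/simulation_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(metrics)))
  message(sprintf("%-32s %.4f", metrics$metric[i], metrics$value[i]))
message("Note: no-D junctions can contain chance >=4 nt matches to a D ",
        "gene; the minimum-run rule cannot distinguish those from real ",
        "heavily-trimmed D contributions.")
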