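#!/usr/bin/env Rscript
# Rearrangement-topology and splice-mode classification of the packaged
# clones. The locus' cluster order (cluster1 < cluster3 < cluster2) forces
# an interpretation for every D-J and J-C pairing; clones whose J lies
# upstream of their D, or whose C lies upstream of their J cluster, cannot
# arise from one precursor by deletional joining / cis-splicing.

suppressPackageStartupMessages(library(trbrep))
dir.create("results", showWarnings = FALSE)

locus <- make_fixture_locus()
clones <- classify_events(load_clone_table(), locus)
write.table(clones, "results/clones_with_event_classes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

r <- table(clones$rearrangement_class)
s <- table(clones$splice_class)
message("Rearrangement classes: ",
        paste(sprintf("%s=%d", names(r), r), collapse = ", "))
message("Splice classes: ",
        paste(sprintf("%s=%d", names(s), s), collapse = ", "))
trans <- clones[clones$rearrangement_class == "trans_rearrangement", ]
message("Trans-rearranged clones (inversion or trans-rearrangement): ",
        paste(sprintf("%s (%s-%s)", trans$clone_id, trans$d_gene,
                      trans$j_gene), collapse = ", "))
tsp <- clones[clones$splice_class == "trans_splice", ]
message(sprintf("Trans-spliced clones: %d, all TRBJ2 joined to %s",
                nrow(tsp),
                paste(sort(unique(tsp$c_gene)), collapse = "/")))
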