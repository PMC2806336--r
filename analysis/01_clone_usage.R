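#!/usr/bin/env Rscript
# Gene usage and CDR3 length statistics of the 72 packaged beta-chain cDNA
# clones. Writes the usage tables and per-group CDR3 statistics under
# results/ and prints the headline figures.

suppressPackageStartupMessages(library(trbrep))
dir.create("results", showWarnings = FALSE)

locus <- make_fixture_locus()
clones <- load_clone_table()
s <- summarize_repertoire(clones, locus)

message(sprintf("Clones: %d (%d with an assigned D gene)",
                s$totals$all_clones, s$totals$d_assigned))
jc <- s$j_cluster_usage
message(sprintf("TRBJ2-cluster usage: %d/%d = %.1f%%",
                jc$n[jc$level == "cluster2"], jc$denominator[1L],
                jc$percent[jc$level == "cluster2"]))
cu <- s$c_usage
message(sprintf("C isotype census: C3 %.1f%%, C2 %.1f%%, C1 %.1f%%",
                cu$percent[cu$level == "TRBC3"],
                cu$percent[cu$level == "TRBC2"],
                cu$percent[cu$level == "TRBC1"]))
du <- s$d_usage
message(sprintf("D usage (of D-assigned): D1 %.1f%%, D3 %.1f%%, D2 %.1f%%",
                du$percent[du$level == "TRBD1"],
                du$percent[du$level == "TRBD3"],
                du$percent[du$level == "TRBD2"]))

for (nm in c("d_usage", "d_usage_all", "j_usage", "j_cluster_usage",
             "j_within_cluster", "c_usage"))
  write.table(s[[nm]], file.path("results", paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

aa <- cdr3_stats(clones, group_by = "tissue", unit = "aa")
nt <- cdr3_stats(clones, group_by = "d_group", unit = "nt")
write.table(aa, "results/cdr3_by_tissue_aa.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(nt, "results/cdr3_by_dgroup_nt.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("CDR3 aa mean by tissue: ",
        paste(sprintf("%s %.1f", aa$group, aa$mean), collapse = ", "))
message("CDR3 nt mean by D group: ",
        paste(sprintf("%s %.1f", nt$group, nt$mean), collapse = ", "))
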