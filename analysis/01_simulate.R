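#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# Builds a ~380,000-probe exon-centric array over six chromosomes and a
# genealogy of 12 selfing isolates with unequal divergence from the
# reference: a couple of highly diverged strains, a near-identical one,
# and one recombinant whose left arm of chromosome II was exchanged.
# Writes the probe map, the ground-truth indel set, per-strain raw ratio
# tables (Gaussian probe noise sd 0.25, cubic intensity bias amplitude
# 0.3), and a synthetic gene catalog.

suppressPackageStartupMessages(library(cghindels))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

layout <- layout_config() # 6 chromosomes, mean spacing 260 bp, arms 38%
probe_map <- generate_probe_map(layout, seed = 2001)
message(sprintf("probe map: %d probes on %d chromosomes",
                nrow(probe_map), length(unique(probe_map$chrom))))

tree <- ape::read.tree(text = paste0(
  "(((S01,S02),(S03,S04)),((S05,S06),(S07,S08)),((S09,S10),(S11,S12)));"))
# terminal rates vary: S01/S02 highly diverged, S12 nearly reference-like
term_rates <- c(S01 = 60L, S02 = 45L, S03 = 25L, S04 = 20L, S05 = 25L,
                S06 = 20L, S07 = 15L, S08 = 18L, S09 = 22L, S10 = 16L,
                S11 = 12L, S12 = 2L)
rates <- ifelse(tree$edge[, 2] <= 12,
                term_rates[tree$tip.label[tree$edge[, 2]]], 8L)

# a recombination event: S07 swaps the left 4 Mb of chromosome II with S02
swaps <- list(list(strains = c("S07", "S02"), chrom = "II",
                   start = 1, end = 4e6))

cohort <- simulate_cohort(probe_map, tree, probe_sd = 0.25,
                          trend_amplitude = 0.3, events_per_branch = rates,
                          recomb_swaps = swaps, seed = 2003)
loci <- attr(cohort$truth, "loci")
message(sprintf("planted %d loci (%s); %d strain-level events",
                nrow(loci),
                paste(names(table(loci$kind)), table(loci$kind),
                      collapse = ", ", sep = ": "),
                nrow(cohort$truth)))

write_probe_map(probe_map, file.path(out, "probe_map.tsv"))
write_boundaries_bed(arm_boundaries(probe_map), file.path(out, "arms.bed"))
write_truth_gff3(cohort$truth, file.path(out, "truth.gff3"))
write.table(cohort$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (s in cohort$strains) {
  write_ratio_table(cohort$profiles[[s]], file.path(out, paste0(s, ".tsv")))
}
genes <- simulate_gene_annotations(probe_map, gene_density = 50, seed = 2005)
write_genes_gff3(genes, file.path(out, "genes.gff3"))
message(sprintf("wrote %d gene annotations and %d ratio tables to %s",
                nrow(genes), length(cohort$strains), out))
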