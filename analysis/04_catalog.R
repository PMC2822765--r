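#!/usr/bin/env Rscript

# Stage 4: the cross-strain indel catalog.
#
# Matches indel alleles across strains (overlapping, breakpoints within 3
# probes, or breakpoints inside the other call's flank span), builds the
# deletion presence/absence matrix, summarizes per-strain counts and
# lengths, the pairwise shared-deletion matrix and sharing spectrum,
# annotates affected genes, and runs the chromosome / strain / arm
# enrichment statistics.

suppressPackageStartupMessages(library(cghindels))

sim <- "results/sim"
out <- "results/catalog"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

probe_map <- read_probe_map(file.path(sim, "probe_map.tsv"))
boundaries <- read_boundaries_bed(file.path(sim, "arms.bed"))
genes <- read_genes_gff3(file.path(sim, "genes.gff3"))
calls <- read_calls_gff3("results/calls/all_strains.calls.gff3")
strains <- sprintf("S%02d", 1:12)

loci <- match_indel_alleles(calls, probe_map, tolerance_probes = 3)
message(sprintf("%d calls -> %d distinguishable loci (%s)",
                nrow(calls), nrow(loci),
                paste(names(table(loci$kind)), table(loci$kind),
                      sep = ": ", collapse = ", ")))
loci_tsv <- loci[, c("locus_id", "kind", "chrom", "left_bp_probe",
                     "right_bp_probe", "start", "end", "n_carriers")]
loci_tsv$carriers <- vapply(loci$carriers, paste, character(1), collapse = ",")
write.table(loci_tsv, file.path(out, "loci.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

pa <- build_presence_absence(loci, strains)
write_pa_matrix(pa, file.path(out, "presence_absence.tsv"))
message(sprintf("presence/absence matrix: %d strains x %d deletion loci",
                nrow(pa), ncol(pa)))

summary <- summarize_catalog(calls, loci, strains, genes)
write.table(summary$per_strain, file.path(out, "per_strain.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summary$pairwise_shared, file.path(out, "pairwise_shared.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
spectrum <- do.call(rbind, lapply(names(summary$sharing_spectrum), function(s) {
  data.frame(strain = s, n_other_strains = names(summary$sharing_spectrum[[s]]),
             n_deletions = as.integer(summary$sharing_spectrum[[s]]))
}))
write.table(spectrum, file.path(out, "sharing_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

dels <- loci[loci$kind == "deletion", , drop = FALSE]
affected <- annotate_genes(dels, genes)
affected$locus_id <- dels$locus_id[affected$row]
write.table(affected[, c("locus_id", "gene_id", "effect", "biotype")],
            file.path(out, "affected_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d genes and %d pseudogenes hit by deletions",
                length(unique(affected$gene_id[affected$biotype == "gene"])),
                length(unique(affected$gene_id[affected$biotype == "pseudogene"]))))

stats <- run_length_and_count_tests(calls, probe_map, boundaries)
message(sprintf("deletions on arms: %.1f%% (arms hold %.1f%% of probes)",
                100 * mean(stats$region[calls$kind == "deletion"] == "arm"),
                100 * mean(probe_map$region == "arm")))
message(sprintf("deletion counts vs probe shares: X2 = %.1f, P = %.3g",
                stats$chisq_deletion$statistic, stats$chisq_deletion$p.value))
if (!is.null(stats$ttest_arm_vs_center)) {
  message(sprintf("arm vs center/X length t-test: t = %.2f, P = %.3g",
                  stats$ttest_arm_vs_center$statistic,
                  stats$ttest_arm_vs_center$p.value))
}
sink(file.path(out, "statistics.txt"))
print(stats$chisq_deletion); print(stats$chisq_amplification)
print(stats$anova_strain); print(stats$anova_chromosome)
print(stats$ttest_arm_vs_center)
sink()
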