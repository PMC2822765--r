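#!/usr/bin/env Rscript

# Stage 5: strain relationships from deletion markers.
#
# 1000 bootstrap replicates over the deletion loci, heuristic parsimony
# search per replicate (10 jumbled addition orders + NNI) under both
# Camin-Sokal and Wagner parsimony, majority-rule consensus with
# per-bipartition support, and a combined CS%/W% tree.

suppressPackageStartupMessages(library(cghindels))

out <- "results/trees"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pa <- read_pa_matrix("results/catalog/presence_absence.tsv")
pa <- pa[, colSums(pa) < nrow(pa), drop = FALSE] # drop fixed columns
message(sprintf("tree inference over %d polymorphic deletion loci", ncol(pa)))

cons <- list()
for (method in c("camin_sokal", "wagner")) {
  cons[[method]] <- bootstrap_consensus(pa, method, n_replicates = 1000,
                                        seed = 2011)
  write_newick(cons[[method]],
               file.path(out, paste0("consensus_", method, ".nwk")))
  maj <- cons[[method]]$support[cons[[method]]$support$pct > 50, ]
  message(sprintf("%s: %d majority bipartitions, support %.0f-%.0f%%",
                  method, nrow(maj), min(maj$pct), max(maj$pct)))
}
write.table(cons$camin_sokal$support, file.path(out, "support_camin_sokal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cons$wagner$support, file.path(out, "support_wagner.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

same <- ape::dist.topo(ape::unroot(cons$camin_sokal$tree),
                       ape::unroot(cons$wagner$tree))[1] == 0
message(sprintf("the two parsimony methods give %s consensus topology",
                if (same) "the same" else "different"))
dual <- dual_support_tree(cons$camin_sokal, cons$wagner)
write_newick(dual, file.path(out, "consensus_dual.nwk"))
message("combined CS/W tree: ", ape::write.tree(dual))

# example group-frequency queries against the replicate archives
for (grp in list(c("S01", "S02"), c("S05", "S06"), c("S07", "S08"))) {
  message(sprintf("group {%s}: on %.0f%% of CS trees, %.0f%% of W trees",
                  paste(grp, collapse = ","),
                  group_frequency(cons$camin_sokal, grp),
                  group_frequency(cons$wagner, grp)))
}
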