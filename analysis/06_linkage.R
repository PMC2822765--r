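#!/usr/bin/env Rscript

# Stage 6: multilocus linkage disequilibrium.
#
# Standardized index of association over the deletion presence/absence
# matrix, with a Monte Carlo null built by permuting each locus's alleles
# among strains (1000 permutations).  In a predominantly selfing species
# the markers travel together, so I_A^S should sit well above its
# equilibrium expectation of 0.

suppressPackageStartupMessages(library(cghindels))

out <- "results/linkage"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pa <- read_pa_matrix("results/catalog/presence_absence.tsv")
pa <- pa[, colSums(pa) < nrow(pa), drop = FALSE]
res <- ia_s_permutation_test(pa, n_permutations = 1000, seed = 2017)
print(res)
message(sprintf("null distribution: mean %.4f, max %.4f",
                mean(res$null), max(res$null)))
writeLines(c(
  sprintf("n_strains\t%d", res$n),
  sprintf("n_loci\t%d", res$l),
  sprintf("V_D\t%.6f", res$V_D),
  sprintf("V_e\t%.6f", res$V_e),
  sprintf("ia_s\t%.6f", res$ia_s),
  sprintf("p_value\t%.6g", res$p_value),
  sprintf("n_permutations\t%d", res$n_permutations)
), file.path(out, "linkage.tsv"))
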