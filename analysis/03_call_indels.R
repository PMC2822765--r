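#!/usr/bin/env Rscript

# Stage 3: segmentation and indel calling.
#
# Bottom-up t-test merging (alpha 0.05), classification at P <= 0.01 with
# mean log2 <= -2 (deletion) / >= +1 (amplification), >= 3 probes with the
# 2-probe very-negative deletion exception, breakpoint and flanking probe
# determination.  Calls are written as GFF3 + BED plus a review TSV with
# +-10 probes of context; recovery against the planted truth is reported.

suppressPackageStartupMessages(library(cghindels))

sim <- "results/sim"
out <- "results/calls"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

probe_map <- read_probe_map(file.path(sim, "probe_map.tsv"))
truth <- read.delim(file.path(sim, "truth.tsv"), stringsAsFactors = FALSE)
strains <- sprintf("S%02d", 1:12)
params <- calling_params()

all_calls <- list()
for (s in strains) {
  prof <- read_ratio_table(file.path(sim, paste0(s, ".norm.tsv")),
                           strain = s, normalized = TRUE)
  calls <- call_indels(prof, probe_map, params)
  write_calls_gff3(calls, file.path(out, paste0(s, ".calls.gff3")))
  write_calls_bed(calls, file.path(out, paste0(s, ".calls.bed")))
  write.table(review_export(calls, prof),
              file.path(out, paste0(s, ".review.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d deletions, %d amplifications",
                  s, sum(calls$kind == "deletion"),
                  sum(calls$kind == "amplification")))
  all_calls[[s]] <- calls
}
combined <- do.call(rbind, all_calls)
class(combined) <- c("indel_calls", "data.frame")
write_calls_gff3(combined, file.path(out, "all_strains.calls.gff3"))

rec <- truth_recovery_metrics(combined, truth, probe_map, min_probes = 3)
be <- rec$breakpoint_errors
message(sprintf(paste0("recovery vs planted truth (>=3 probes): ",
                       "sensitivity %.3f, FDR %.3f, ",
                       "%.1f%% of breakpoints within +-1 probe"),
                rec$sensitivity, rec$fdr,
                100 * mean(abs(be$left_error) <= 1 & abs(be$right_error) <= 1)))
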