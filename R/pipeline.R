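#' Load a pipeline configuration
#'
#' Flat YAML configuration for [run_pipeline()].  Recognised keys:
#' `probe_map` (path), `ratios` (map of strain label to ratio TSV path),
#' `genes` (optional GFF3), `boundaries` (optional arm BED; derived from
#' the probe map's labels when absent), `out_dir`, `reference_strain`,
#' `normalize` (logical), `span`, calling thresholds (`merge_alpha`,
#' `segment_p_cutoff`, `deletion_cutoff`, `amplification_cutoff`,
#' `min_probes`), and popgen settings (`replicates`, `permutations`,
#' `seed`).  All thresholds default to the pipeline's standard operating
#' point (0.05, 0.01, -2, +1, 3, -0.8, +0.5, 1000).
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("probe_map", "ratios", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("config lacks required field: %s", miss[1])
  paths <- c(cfg$probe_map, unlist(cfg$ratios), cfg$genes, cfg$boundaries)
  if (anyDuplicated(paths)) stopf("config paths must be distinct")
  cfg$reference_strain <- cfg$reference_strain %||% "reference"
  if (cfg$reference_strain %in% names(cfg$ratios)) {
    stopf(paste("reference strain '%s' must not appear among the ratio tables;",
                "ratios are isolate/reference so it carries no markers"),
          cfg$reference_strain)
  }
  cfg$normalize <- cfg$normalize %||% TRUE
  cfg$span <- cfg$span %||% 0.4
  cfg$replicates <- cfg$replicates %||% 1000L
  cfg$permutations <- cfg$permutations %||% 1000L
  cfg$seed <- cfg$seed %||% 1L
  cfg$params <- calling_params(
    merge_alpha = cfg$merge_alpha %||% 0.05,
    segment_p_cutoff = cfg$segment_p_cutoff %||% 0.01,
    deletion_cutoff = cfg$deletion_cutoff %||% -2,
    amplification_cutoff = cfg$amplification_cutoff %||% 1,
    min_probes = cfg$min_probes %||% 3L
  )
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline from ratio tables to trees and LD
#'
#' Chains every stage: read the probe map and per-strain ratio tables,
#' normalize, call indels (written as GFF3, BED and a review TSV per
#' strain), match alleles into loci, build the deletion presence/absence
#' matrix, summarize the catalog, run the enrichment statistics, infer
#' bootstrap consensus trees under both parsimony methods (written as
#' Newick, including one tree labeled with combined `CS%/W%` support),
#' and test multilocus linkage disequilibrium.  Each stage logs its
#' parameters and input checksums so any number in a report is traceable.
#'
#' @param config A [pipeline_config()] (or path to one).
#' @return Invisibly, a list with calls, loci, matrix, summaries,
#'   statistics, consensus trees and the LD result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  probe_map <- read_probe_map(config$probe_map)
  log_stage("input", "probe map %s (%d probes, md5 %s)", config$probe_map,
            nrow(probe_map), tools::md5sum(config$probe_map)[[1]])
  boundaries <- if (!is.null(config$boundaries)) {
    read_boundaries_bed(config$boundaries)
  } else {
    arm_boundaries(probe_map)
  }
  genes <- if (!is.null(config$genes)) read_genes_gff3(config$genes) else NULL

  strains <- names(config$ratios)
  calls <- lapply(strains, function(s) {
    prof <- read_ratio_table(config$ratios[[s]], strain = s,
                             normalized = !config$normalize)
    if (config$normalize) prof <- lowess_normalize(prof, span = config$span)
    cl <- call_indels(prof, probe_map, config$params)
    log_stage("call", "%s: %d calls (alpha=%g, p<=%g, del<=%g, amp>=%g)",
              s, nrow(cl), config$params$merge_alpha,
              config$params$segment_p_cutoff, config$params$deletion_cutoff,
              config$params$amplification_cutoff)
    write_calls_gff3(cl, file.path(config$out_dir, paste0(s, ".calls.gff3")))
    write_calls_bed(cl, file.path(config$out_dir, paste0(s, ".calls.bed")))
    write.table(review_export(cl, prof),
                file.path(config$out_dir, paste0(s, ".review.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cl
  })
  all_calls <- do.call(rbind, calls)
  class(all_calls) <- c("indel_calls", "data.frame")

  loci <- match_indel_alleles(all_calls, probe_map)
  pa <- build_presence_absence(loci, strains)
  pa_poly <- pa[, colSums(pa) < nrow(pa), drop = FALSE] # drop fixed columns
  write_pa_matrix(pa, file.path(config$out_dir, "presence_absence.tsv"))

  summary <- summarize_catalog(all_calls, loci, strains, genes)
  write.table(summary$per_strain, file.path(config$out_dir, "per_strain.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary$pairwise_shared,
              file.path(config$out_dir, "pairwise_shared.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  stats <- run_length_and_count_tests(all_calls, probe_map, boundaries)

  seeds <- derive_child_seeds(config$seed, 3L)
  cons <- list()
  if (ncol(pa_poly) >= 2 && length(strains) >= 4) {
    cons$camin_sokal <- bootstrap_consensus(pa_poly, "camin_sokal",
                                            n_replicates = config$replicates,
                                            seed = seeds[1])
    cons$wagner <- bootstrap_consensus(pa_poly, "wagner",
                                       n_replicates = config$replicates,
                                       seed = seeds[2])
    write_newick(cons$camin_sokal,
                 file.path(config$out_dir, "consensus_camin_sokal.nwk"))
    write_newick(cons$wagner, file.path(config$out_dir, "consensus_wagner.nwk"))
    write_newick(dual_support_tree(cons$camin_sokal, cons$wagner),
                 file.path(config$out_dir, "consensus_dual.nwk"))
  }
  ld <- if (ncol(pa_poly) >= 2 && length(strains) >= 3) {
    res <- ia_s_permutation_test(pa_poly, n_permutations = config$permutations,
                                 seed = seeds[3])
    writeLines(sprintf("ia_s\t%.6f\np_value\t%.6g\nn_permutations\t%d",
                       res$ia_s, res$p_value, res$n_permutations),
               file.path(config$out_dir, "linkage.tsv"))
    res
  } else {
    NULL
  }
  invisible(list(calls = all_calls, loci = loci, matrix = pa,
                 summary = summary, stats = stats, consensus = cons, ld = ld))
}

#' Consensus tree labeled with support under both parsimony methods
#'
#' Takes the Camin-Sokal consensus topology and labels each bipartition
#' with `"CS%/W%"`: its support under Camin-Sokal and its replicate
#' frequency under Wagner (queried from the Wagner archive, so the label
#' is defined even where the Wagner consensus differs).
#'
#' @param cons_cs,cons_w [bootstrap_consensus()] results for the two
#'   methods.
#' @return An `ape::phylo` with combined node labels.
#' @export
dual_support_tree <- function(cons_cs, cons_w) {
  strains <- sort(cons_cs$tree$tip.label)
  keys <- split_keys(cons_cs$tree)$all
  sup <- cons_cs$support
  splits <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  labels <- vapply(keys, function(k) {
    cs_pct <- sup$pct[match(k, sup$split)]
    w_pct <- group_frequency(cons_w, strsplit(k, "|", fixed = TRUE)[[1]],
                             strains = strains)
    sprintf("%g/%g", round(cs_pct, 0), round(w_pct, 0))
  }, character(1))
  tree_from_splits(splits, cons_cs$tree$tip.label, labels)
}
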