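#' Noise configuration for the forward model
#'
#' @param probe_sd Standard deviation of per-probe Gaussian log2 noise.
#' @param trend_amplitude Magnitude of the smooth intensity-dependent dye
#'   bias added to the log2 ratios (0 disables the trend).
#' @param seed Integer seed.
#' @return A `noise_config` list.
#' @export
noise_config <- function(probe_sd = 0.25, trend_amplitude = 0, seed = 1L) {
  if (probe_sd < 0) stopf("probe_sd must be >= 0")
  structure(list(probe_sd = probe_sd, trend_amplitude = trend_amplitude,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Simulate a raw per-strain ratio profile
#'
#' Forward model for a two-color aCGH experiment comparing one strain
#' against the reference.  Probes overlapping a truth indel take that
#' indel's expected log2 shift (boundary probes partially overlapping an
#' indel get the full signal); all other probes are 0.  Gaussian noise with
#' sd `noise$probe_sd` is added.  A per-probe mean log-intensity covariate
#' `A` is drawn uniformly on `[8, 16]` and a smooth cubic dye bias of
#' amplitude `noise$trend_amplitude` in `A` is added to the ratios, giving
#' the LOWESS normalization a non-linear target.  Test and reference
#' intensities are then reconstructed so that `(log2(test) +
#' log2(ref)) / 2 = A` and `log2(test / ref)` equals the simulated ratio.
#'
#' @param probe_map A [generate_probe_map()] result.
#' @param truth Truth rows for this strain (subset of a
#'   [simulate_genealogy_truth()] result, or any data frame with columns
#'   `chrom`, `start`, `end`, `signal_log2`).
#' @param noise A [noise_config()].
#' @param strain Strain label recorded on the profile.
#' @return A `data.frame` of class `ratio_profile` with columns `probe_id`,
#'   `chrom`, `start`, `end`, `test_intensity`, `ref_intensity`,
#'   `log2_ratio`; attributes `strain` and `normalized` (FALSE).
#' @export
simulate_ratio_profile <- function(probe_map, truth, noise = noise_config(),
                                   strain = "strain1") {
  check_probe_map(probe_map)
  if (nrow(truth) > 0 && !all(truth$chrom %in% probe_map$chrom)) {
    stopf("truth indels must lie on probe map chromosomes")
  }
  n <- nrow(probe_map)
  by_chrom <- split(seq_len(n), probe_map$chrom)
  signal <- numeric(n)
  for (i in seq_len(nrow(truth))) {
    rows <- by_chrom[[truth$chrom[i]]]
    cm <- probe_map[rows, , drop = FALSE]
    idx <- probes_in_interval(cm, truth$start[i], truth$end[i])
    signal[rows[idx]] <- truth$signal_log2[i]
  }
  with_seed(noise$seed, {
    A <- runif(n, 8, 16)
    bias <- noise$trend_amplitude * (2 * (A - 8) / 8 - 1)^3
    ratio <- signal + bias + rnorm(n, sd = noise$probe_sd)
    prof <- data.frame(
      probe_id = probe_map$probe_id,
      chrom = probe_map$chrom,
      start = probe_map$start,
      end = probe_map$end,
      test_intensity = 2^(A + ratio / 2),
      ref_intensity = 2^(A - ratio / 2),
      log2_ratio = ratio,
      stringsAsFactors = FALSE
    )
    new_ratio_profile(prof, strain = strain, normalized = FALSE)
  })
}

new_ratio_profile <- function(df, strain, normalized) {
  attr(df, "strain") <- strain
  attr(df, "normalized") <- normalized
  class(df) <- c("ratio_profile", "data.frame")
  df
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("ratio_profile: strain %s, %d probes, %s\n",
              attr(x, "strain"), nrow(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw"))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Simulate a full strain cohort
#'
#' Convenience wrapper: plants a truth set on a genealogy and simulates one
#' raw ratio profile per strain.  Per-strain noise seeds are derived
#' deterministically from the root seed.
#'
#' @inheritParams simulate_genealogy_truth
#' @param probe_sd,trend_amplitude Forwarded to [noise_config()].
#' @param ... Additional arguments to [simulate_genealogy_truth()].
#' @return List with `probe_map`, `truth`, `profiles` (named list of
#'   `ratio_profile`s, one per strain in the tree), and `strains`.
#' @export
simulate_cohort <- function(probe_map, tree_spec, probe_sd = 0.25,
                            trend_amplitude = 0, seed = 1L, ...) {
  seeds <- derive_child_seeds(seed, 2L)
  truth <- simulate_genealogy_truth(probe_map, tree_spec, seed = seeds[1], ...)
  tree <- attr(truth, "tree")
  strains <- tree$tip.label
  strain_seeds <- derive_child_seeds(seeds[2], length(strains))
  profiles <- lapply(seq_along(strains), function(i) {
    simulate_ratio_profile(
      probe_map,
      truth[truth$strain == strains[i], , drop = FALSE],
      noise_config(probe_sd = probe_sd, trend_amplitude = trend_amplitude,
                   seed = strain_seeds[i]),
      strain = strains[i]
    )
  })
  names(profiles) <- strains
  list(probe_map = probe_map, truth = truth, profiles = profiles,
       strains = strains)
}

#' Simulate a gene annotation table
#'
#' Generates a synthetic, non-overlapping gene catalog over the probe map's
#' chromosomes for exercising [annotate_genes()] and the affected-gene
#' summaries; a configurable fraction of entries are flagged pseudogenes.
#'
#' @param probe_map A probe map (defines chromosome extents).
#' @param gene_density Mean genes per Mb.
#' @param mean_length Mean gene length (bp, exponential).
#' @param pseudogene_fraction Fraction annotated as pseudogenes.
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `biotype`.
#' @export
simulate_gene_annotations <- function(probe_map, gene_density = 50,
                                      mean_length = 3000,
                                      pseudogene_fraction = 0.1, seed = 1L) {
  check_probe_map(probe_map)
  extents <- tapply(probe_map$end, probe_map$chrom, max)
  with_seed(seed, {
    out <- lapply(names(extents), function(chrom) {
      len <- extents[[chrom]]
      n <- max(1, round(gene_density * len / 1e6))
      gap <- len / n
      starts <- floor((seq_len(n) - 1) * gap + runif(n, 1, gap * 0.3))
      ends <- pmin(len, starts + pmax(200, round(rexp(n, 1 / mean_length))))
      ends <- pmin(ends, c(starts[-1] - 1, len)) # keep genes non-overlapping
      keep <- ends > starts
      data.frame(chrom = chrom, start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]), stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, out)
    genes$gene_id <- sprintf("G%s_%05d", genes$chrom,
                             unlist(lapply(out, function(x) seq_len(nrow(x)))))
    genes$biotype <- ifelse(runif(nrow(genes)) < pseudogene_fraction,
                            "pseudogene", "gene")
    rownames(genes) <- NULL
    genes[, c("gene_id", "chrom", "start", "end", "biotype")]
  })
}
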