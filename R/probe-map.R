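#' Layout configuration for a synthetic exon-centric tiling array
#'
#' Describes the genome and array geometry used by [generate_probe_map()].
#' The defaults emulate a whole-genome exon-centric array on the six
#' *C. elegans* chromosomes: roughly 100 Mb of sequence tiled at a mean
#' probe spacing of 260 bp, for ~380,000 probes.  Autosomes are split into
#' two recombination-rich arms and a center; the arms jointly hold about
#' 38% of all probes (`arm_fraction = 0.23` of each autosome per arm, with the X armless).  The X chromosome is
#' treated as a single region with no arm/center distinction.
#'
#' @param chromosome_names Character vector of chromosome labels.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp,
#'   parallel to `chromosome_names`.
#' @param probe_spacing_mean Mean start-to-start distance between adjacent
#'   probes, in bp.
#' @param probe_length Probe length in bp.
#' @param arm_fraction Fraction of each autosome's probes assigned to *each*
#'   arm (so the two arms together hold `2 * arm_fraction`).
#' @param x_chromosome Label of the chromosome treated as X (no arms).
#'
#' @return A `layout_config` list.
#' @export
layout_config <- function(chromosome_names = c("I", "II", "III", "IV", "V", "X"),
                          chromosome_lengths = c(15.1e6, 15.3e6, 13.8e6,
                                                 17.5e6, 20.9e6, 17.7e6),
                          probe_spacing_mean = 260,
                          probe_length = 50,
                          arm_fraction = 0.23,
                          x_chromosome = "X") {
  if (length(chromosome_names) != length(chromosome_lengths)) {
    stopf("chromosome_names and chromosome_lengths must have equal length")
  }
  if (anyDuplicated(chromosome_names)) stopf("duplicate chromosome names")
  if (any(chromosome_lengths <= 0)) stopf("all chromosome lengths must be positive")
  if (!(probe_spacing_mean > probe_length && probe_length > 0)) {
    stopf("need probe_spacing_mean > probe_length > 0")
  }
  if (!(arm_fraction > 0 && 2 * arm_fraction < 1)) {
    stopf("need 0 < 2 * arm_fraction < 1")
  }
  structure(
    list(
      chromosome_names = as.character(chromosome_names),
      chromosome_lengths = as.numeric(chromosome_lengths),
      probe_spacing_mean = probe_spacing_mean,
      probe_length = probe_length,
      arm_fraction = arm_fraction,
      x_chromosome = x_chromosome
    ),
    class = "layout_config"
  )
}

#' Generate an ordered genomic probe map
#'
#' Tiles each chromosome with non-overlapping probes whose start-to-start
#' spacing is exponentially jittered around `layout$probe_spacing_mean`
#' (truncated below at the probe length, so probes never overlap).  On
#' autosomes the first and last `arm_fraction` of probes (by count) are
#' labeled `"arm"` and the middle `"center"`; every probe on the X
#' chromosome is labeled `"X"`.
#'
#' @param layout A [layout_config()].
#' @param seed Integer seed; the same seed always yields the same map.
#'
#' @return A `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), `region`
#'   (`arm`/`center`/`X`) and `index` (1-based probe index within its
#'   chromosome), sorted by `(chrom, start)`.
#' @export
generate_probe_map <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "layout_config"))
  if (any(layout$chromosome_lengths < layout$probe_length)) {
    stopf("chromosome shorter than one probe")
  }
  gap_mean <- layout$probe_spacing_mean - layout$probe_length
  pieces <- with_seed(seed, {
    lapply(seq_along(layout$chromosome_names), function(i) {
      chrom <- layout$chromosome_names[i]
      len <- layout$chromosome_lengths[i]
      # draw enough gaps to cover the chromosome, then truncate
      n_guess <- ceiling(len / layout$probe_spacing_mean * 1.3) + 10
      gaps <- layout$probe_length + rexp(n_guess, rate = 1 / gap_mean)
      starts <- floor(1 + cumsum(c(0, gaps)))
      starts <- starts[starts + layout$probe_length - 1 <= len]
      n <- length(starts)
      region <- if (identical(chrom, layout$x_chromosome)) {
        rep("X", n)
      } else {
        n_arm <- floor(layout$arm_fraction * n)
        r <- rep("center", n)
        if (n_arm > 0) {
          r[seq_len(n_arm)] <- "arm"
          r[seq.int(n - n_arm + 1L, n)] <- "arm"
        }
        r
      }
      data.frame(
        chrom = chrom,
        start = as.integer(starts),
        end = as.integer(starts + layout$probe_length - 1),
        region = region,
        index = seq_len(n),
        stringsAsFactors = FALSE
      )
    })
  })
  map <- do.call(rbind, pieces)
  map$probe_id <- sprintf("P%s_%06d", map$chrom, map$index)
  map <- map[, c("probe_id", "chrom", "start", "end", "region", "index")]
  rownames(map) <- NULL
  class(map) <- c("probe_map", "data.frame")
  map
}

#' Arm/center boundary intervals implied by a probe map
#'
#' Derives, for each autosome, the two arm intervals spanned by the probes
#' labeled `arm`.  These are the interval definitions consumed by
#' [assign_region()] and written to BED.
#'
#' @param probe_map A [generate_probe_map()] result.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) covering the arm intervals.
#' @export
arm_boundaries <- function(probe_map) {
  arm <- probe_map[probe_map$region == "arm", , drop = FALSE]
  if (nrow(arm) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(arm, arm$chrom), function(a) {
    # two runs of consecutive indices: left arm and right arm
    brk <- c(0, which(diff(a$index) > 1), nrow(a))
    runs <- lapply(seq_len(length(brk) - 1), function(k) {
      seg <- a[(brk[k] + 1):brk[k + 1], , drop = FALSE]
      data.frame(chrom = seg$chrom[1], start = min(seg$start),
                 end = max(seg$end), stringsAsFactors = FALSE)
    })
    do.call(rbind, runs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Validate that a data frame is a usable probe map; returns it invisibly.
check_probe_map <- function(probe_map) {
  need <- c("probe_id", "chrom", "start", "end", "region", "index")
  if (!all(need %in% names(probe_map))) {
    stopf("probe map lacks columns: %s",
          paste(setdiff(need, names(probe_map)), collapse = ", "))
  }
  invisible(probe_map)
}
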