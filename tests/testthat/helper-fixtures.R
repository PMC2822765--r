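# Small fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_layout <- function(len = 1e5, chroms = "I") {
  layout_config(chromosome_names = chroms,
                chromosome_lengths = rep(len, length(chroms)),
                probe_spacing_mean = 260, probe_length = 50,
                arm_fraction = 0.25, x_chromosome = "X")
}

# a profile with given per-probe ratios on one uniform chromosome
manual_profile <- function(x, chrom = "c1", strain = "s1", normalized = TRUE,
                           spacing = 260, probe_len = 50) {
  n <- length(x)
  starts <- 1 + (seq_len(n) - 1) * spacing
  df <- data.frame(
    probe_id = sprintf("P%s_%06d", chrom, seq_len(n)),
    chrom = chrom,
    start = starts,
    end = starts + probe_len - 1,
    test_intensity = 2^(12 + x / 2),
    ref_intensity = 2^(12 - x / 2),
    log2_ratio = x,
    stringsAsFactors = FALSE
  )
  attr(df, "strain") <- strain
  attr(df, "normalized") <- normalized
  class(df) <- c("ratio_profile", "data.frame")
  df
}

probe_map_for <- function(profile) {
  out <- lapply(split(profile, profile$chrom), function(cm) {
    data.frame(probe_id = cm$probe_id, chrom = cm$chrom, start = cm$start,
               end = cm$end, region = "center", index = seq_len(nrow(cm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[unique(profile$chrom)])
  rownames(out) <- NULL
  class(out) <- c("probe_map", "data.frame")
  out
}

# a minimal call row for matching / annotation tests, defined by probe
# indices on a probe map
manual_call <- function(probe_map, chrom, left, right, strain = "s1",
                        kind = "deletion", left_flank = NULL,
                        right_flank = NULL) {
  cm <- probe_map[probe_map$chrom == chrom, , drop = FALSE]
  # flanks adjacent to the breakpoints unless stated (the common case)
  left_flank <- left_flank %||% (if (left > 1) left - 1L else NA_integer_)
  right_flank <- right_flank %||%
    (if (right < nrow(cm)) right + 1L else NA_integer_)
  data.frame(
    strain = strain, chrom = chrom, kind = kind,
    left_bp_probe = cm$probe_id[left], right_bp_probe = cm$probe_id[right],
    left_index = left, right_index = right,
    start = cm$start[left], end = cm$end[right],
    mean_log2 = if (kind == "deletion") -3 else 1.5,
    p_value = 1e-6, n_probes = right - left + 1L,
    length_bp = (cm$start[right] + cm$end[right]) / 2 -
      (cm$start[left] + cm$end[left]) / 2,
    left_flank_index = left_flank, right_flank_index = right_flank,
    left_flank_probe = if (is.na(left_flank)) NA_character_ else cm$probe_id[left_flank],
    right_flank_probe = if (is.na(right_flank)) NA_character_ else cm$probe_id[right_flank],
    stringsAsFactors = FALSE
  )
}

bind_calls <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("indel_calls", "data.frame")
  out
}

# presence/absence matrix straight from a planted truth set
truth_pa_matrix <- function(truth, strains) {
  loci <- attr(truth, "loci")
  pa <- matrix(0L, length(strains), nrow(loci),
               dimnames = list(strains, loci$locus_id))
  for (k in seq_len(nrow(loci))) {
    pa[intersect(loci$carriers[[k]], strains), k] <- 1L
  }
  pa
}
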