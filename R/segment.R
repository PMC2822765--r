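#' Calling parameters for segment classification
#'
#' Bundles the thresholds of the indel-calling stage.  Defaults are the
#' standard operating point for two-color aCGH deletion screens: segments
#' are aberrant when their one-sample t-test P is at most 0.01 and their
#' mean log2 ratio is at most -2 (deletions) or at least +1
#' (amplifications); aberrant segments need at least 3 probes, except
#' 2-probe deletion candidates where both probes are at or below -2; the
#' flanking-probe thresholds are -0.8 (deletions) and +0.5
#' (amplifications).
#'
#' @param merge_alpha Critical value at which bottom-up merging stops.
#' @param segment_p_cutoff One-sample t-test P cutoff for aberrant calls.
#' @param deletion_cutoff Mean log2 at or below which a segment may be a
#'   deletion.
#' @param amplification_cutoff Mean log2 at or above which a segment may
#'   be an amplification.
#' @param min_probes Minimum probes per aberrant segment.
#' @param two_probe_deletion_cutoff Both probes of a 2-probe segment must
#'   be at or below this to qualify for the 2-probe deletion exception.
#' @param deletion_flank_threshold Ratios above this mark a return to
#'   normal outside a deletion.
#' @param amplification_flank_threshold Ratios below this mark a return to
#'   normal outside an amplification.
#' @return A `calling_params` list.
#' @export
calling_params <- function(merge_alpha = 0.05,
                           segment_p_cutoff = 0.01,
                           deletion_cutoff = -2,
                           amplification_cutoff = 1,
                           min_probes = 3L,
                           two_probe_deletion_cutoff = -2,
                           deletion_flank_threshold = -0.8,
                           amplification_flank_threshold = 0.5) {
  if (!(deletion_cutoff < deletion_flank_threshold &&
        deletion_flank_threshold < 0 &&
        0 < amplification_flank_threshold &&
        amplification_flank_threshold < amplification_cutoff)) {
    stopf("need deletion_cutoff < deletion_flank_threshold < 0 < amplification_flank_threshold < amplification_cutoff")
  }
  if (!(merge_alpha > 0 && merge_alpha < 1 &&
        segment_p_cutoff > 0 && segment_p_cutoff < 1)) {
    stopf("merge_alpha and segment_p_cutoff must lie in (0, 1)")
  }
  structure(list(
    merge_alpha = merge_alpha,
    segment_p_cutoff = segment_p_cutoff,
    deletion_cutoff = deletion_cutoff,
    amplification_cutoff = amplification_cutoff,
    min_probes = as.integer(min_probes),
    two_probe_deletion_cutoff = two_probe_deletion_cutoff,
    deletion_flank_threshold = deletion_flank_threshold,
    amplification_flank_threshold = amplification_flank_threshold
  ), class = "calling_params")
}

# Robust per-chromosome noise SD: scaled median absolute successive
# difference.  For x_i iid N(mu_i, sigma^2) with mostly constant mu,
# |x_{i+1} - x_i| has median sigma * sqrt(2) * qnorm(0.75).
global_noise_sd <- function(x) {
  if (length(x) < 2) return(0)
  median(abs(diff(x))) / (sqrt(2) * qnorm(0.75))
}

# One-sample test P against 0.  Segments with fewer than 3 probes carry
# essentially no variance information of their own (0 or 1 degrees of
# freedom), so the global noise SD stands in and the test is a z-test;
# zero-variance cases have P 0 or 1 by limit.
one_sample_p <- function(x, global_sd) {
  n <- length(x)
  m <- mean(x)
  if (n < 3) {
    if (global_sd <= 0) return(if (m == 0) 1 else 0)
    return(2 * pnorm(-abs(m / (global_sd / sqrt(n)))))
  }
  s <- sd(x)
  if (s == 0) return(if (m == 0) 1 else 0)
  2 * pt(-abs(m / (s / sqrt(n))), df = n - 1)
}

#' Segment a normalized profile by bottom-up t-test merging
#'
#' Starts with every probe as a singleton segment and repeatedly merges
#' the adjacent pair whose Welch two-sample t-test has the largest P value
#' (the pair most likely to share a mean), updating the merged segment's
#' statistics and its tests against both neighbours, until the largest
#' remaining P falls below `merge_alpha`.  Chromosomes are segmented
#' independently; segments never span chromosomes.
#'
#' @param profile A normalized `ratio_profile`.
#' @param merge_alpha Stop threshold for merging (the typical critical
#'   value is 0.05).
#' @return A `data.frame` of class `segment_table`: `chrom`,
#'   `first_probe`, `last_probe` (1-based probe indices within the
#'   chromosome), `n_probes`, `mean_log2`, `p_value` (`NA` until
#'   classification) and `label` (`"unlabeled"`).  Per-chromosome ratios
#'   and noise SDs ride along as attributes for the classification stage.
#' @export
segment_profile <- function(profile, merge_alpha = 0.05) {
  chroms <- unique(profile$chrom)
  ratios <- lapply(chroms, function(ch) profile$log2_ratio[profile$chrom == ch])
  names(ratios) <- chroms
  noise_sd <- vapply(ratios, global_noise_sd, numeric(1))
  pieces <- lapply(chroms, function(ch) {
    x <- ratios[[ch]]
    res <- bottom_up_segment_cpp(x, merge_alpha, noise_sd[[ch]])
    data.frame(
      chrom = ch,
      first_probe = res$first,
      last_probe = res$last,
      n_probes = res$last - res$first + 1L,
      mean_log2 = vapply(seq_along(res$first), function(i) {
        mean(x[res$first[i]:res$last[i]])
      }, numeric(1)),
      p_value = NA_real_,
      label = "unlabeled",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  attr(out, "noise_sd") <- noise_sd
  attr(out, "strain") <- attr(profile, "strain")
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Classify segments as deletions, amplifications or normal
#'
#' Each segment receives a one-sample t-test P value against 0 and is
#' labeled a deletion (mean at or below the deletion cutoff, P at or below
#' the cutoff) or an amplification (mean at or above the amplification
#' cutoff); 2-probe segments whose two ratios are both at or below the
#' 2-probe deletion cutoff are labeled deletions regardless of their own P
#' (with one degree of freedom the t-test is essentially powerless, which
#' is the reason this class of very negative 2-probe segments is treated
#' separately).  Adjacent segments sharing a label are then merged and
#' their statistics recomputed, and aberrant segments with fewer than
#' `min_probes` probes are relabeled normal unless they qualify for the
#' 2-probe deletion exception.
#'
#' @param segments A `segment_table` from [segment_profile()].
#' @param params A [calling_params()].
#' @return The segment table with `p_value` and `label` filled in.
#' @export
classify_and_filter <- function(segments, params = calling_params()) {
  ratios <- attr(segments, "ratios")
  noise_sd <- attr(segments, "noise_sd")
  if (is.null(ratios)) stopf("segments must come from segment_profile()")

  pieces <- lapply(split(segments, segments$chrom), function(sg) {
    sg <- sg[order(sg$first_probe), , drop = FALSE]
    ch <- sg$chrom[1]
    x <- ratios[[ch]]
    gsd <- noise_sd[[ch]]
    cs <- c(0, cumsum(x))
    css <- c(0, cumsum(x * x))

    stats_for <- function(first, last) {
      n <- last - first + 1L
      sm <- cs[last + 1] - cs[first]
      ss <- css[last + 1] - css[first]
      m <- sm / n
      v <- pmax(0, (ss - sm^2 / n) / pmax(1, n - 1))
      s <- sqrt(v)
      p <- numeric(length(n))
      # below 3 probes a sample variance has at most 1 df and is useless;
      # the global noise SD stands in and the test becomes a z-test
      multi <- n >= 3
      pos <- multi & s > 0
      p[pos] <- 2 * pt(-abs(m[pos] / (s[pos] / sqrt(n[pos]))), df = n[pos] - 1)
      p[multi & s == 0] <- as.numeric(m[multi & s == 0] == 0)
      small <- !multi
      if (gsd > 0) {
        p[small] <- 2 * pnorm(-abs(m[small] / (gsd / sqrt(n[small]))))
      } else {
        p[small] <- as.numeric(m[small] == 0)
      }
      list(n = n, m = m, p = p)
    }
    label_for <- function(first, last, st) {
      lab <- rep("normal", length(first))
      lab[st$m <= params$deletion_cutoff & st$p <= params$segment_p_cutoff] <- "deletion"
      lab[st$m >= params$amplification_cutoff & st$p <= params$segment_p_cutoff] <- "amplification"
      # 2-probe deletion exception: both probes very negative
      two <- st$n == 2 & lab == "normal" & st$m <= params$deletion_cutoff &
        x[first] <= params$two_probe_deletion_cutoff &
        x[last] <= params$two_probe_deletion_cutoff
      lab[two] <- "deletion"
      lab
    }

    st <- stats_for(sg$first_probe, sg$last_probe)
    lab <- label_for(sg$first_probe, sg$last_probe, st)

    # merge runs of adjacent same-label segments, recompute statistics
    run <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
    first <- as.integer(tapply(sg$first_probe, run, min))
    last <- as.integer(tapply(sg$last_probe, run, max))
    lab <- as.character(tapply(lab, run, function(v) v[1]))
    st <- stats_for(first, last)

    # minimum-probe filter with the 2-probe deletion exception
    small <- lab %in% c("deletion", "amplification") & st$n < params$min_probes
    keep <- lab == "deletion" & st$n == 2 &
      x[first] <= params$two_probe_deletion_cutoff &
      x[last] <= params$two_probe_deletion_cutoff
    lab[small & !keep] <- "normal"

    data.frame(chrom = ch, first_probe = first, last_probe = last,
               n_probes = st$n, mean_log2 = st$m, p_value = st$p,
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  attr(out, "noise_sd") <- noise_sd
  attr(out, "strain") <- attr(segments, "strain")
  class(out) <- c("segment_table", "data.frame")
  out
}

# scan outward from a breakpoint for the first probe at which normal
# ratios consistently reappear: the probe must satisfy the threshold and
# at least 2 of the 3 probes beyond it (fewer near the chromosome end)
# must satisfy it too
scan_flank <- function(x, from, step, satisfies) {
  n <- length(x)
  j <- from + step
  while (j >= 1 && j <= n) {
    if (satisfies(x[j])) {
      follow <- j + step * (1:3)
      follow <- follow[follow >= 1 & follow <= n]
      need <- min(2L, length(follow))
      if (sum(satisfies(x[follow])) >= need) return(j)
    }
    j <- j + step
  }
  NA_integer_
}

#' Locate flanking probes for an indel call
#'
#' Probes immediately outside an indel sometimes show unusual ratios, so
#' the breakpoint alone does not mark where normal hybridization resumes.
#' Scanning outward from each breakpoint probe, the flank is the first
#' probe whose ratio is back past the threshold (above -0.8 for deletions,
#' below +0.5 for amplifications) such that at least 2 of the 3 probes
#' beyond it are too; absent (`NA`) if the chromosome ends first.
#'
#' @param profile The normalized profile the call was made on.
#' @param call A single-row indel call (from [call_indels()]).
#' @param params A [calling_params()].
#' @return The call row with `left_flank_index`/`right_flank_index` and
#'   the corresponding probe ids filled in.
#' @export
find_flanking_probes <- function(profile, call, params = calling_params()) {
  x <- profile$log2_ratio[profile$chrom == call$chrom]
  ids <- profile$probe_id[profile$chrom == call$chrom]
  satisfies <- if (call$kind == "deletion") {
    function(v) v > params$deletion_flank_threshold
  } else {
    function(v) v < params$amplification_flank_threshold
  }
  lf <- scan_flank(x, call$left_index, -1L, satisfies)
  rf <- scan_flank(x, call$right_index, +1L, satisfies)
  call$left_flank_index <- lf
  call$right_flank_index <- rf
  call$left_flank_probe <- if (is.na(lf)) NA_character_ else ids[lf]
  call$right_flank_probe <- if (is.na(rf)) NA_character_ else ids[rf]
  call
}

#' Call indels on a normalized profile
#'
#' Full calling pipeline for one strain: bottom-up segmentation
#' ([segment_profile()]), classification and filtering
#' ([classify_and_filter()]), then one call per aberrant segment with
#' breakpoint probes (the leftmost and rightmost affected probes),
#' flanking probes ([find_flanking_probes()]) and the indel length
#' measured from the middle of the left breakpoint probe to the middle of
#' the right breakpoint probe.
#'
#' @param profile A normalized `ratio_profile` aligned to `probe_map`.
#' @param probe_map The probe map.
#' @param params A [calling_params()].
#' @return A `data.frame` of class `indel_calls`, sorted by
#'   (chromosome, start): `strain`, `chrom`, `kind`, `left_bp_probe`,
#'   `right_bp_probe`, `left_index`, `right_index` (probe indices within
#'   the chromosome), flank probes/indices, `start`/`end` (bp span of the
#'   breakpoint probes), `mean_log2`, `p_value`, `n_probes`, `length_bp`.
#' @export
call_indels <- function(profile, probe_map, params = calling_params()) {
  check_probe_map(probe_map)
  if (!identical(profile$probe_id, probe_map$probe_id)) {
    stopf("profile probes do not align with the probe map")
  }
  if (!isTRUE(attr(profile, "normalized"))) {
    warnf("profile is not flagged normalized; calling on raw ratios")
  }
  segs <- classify_and_filter(segment_profile(profile, params$merge_alpha), params)
  ab <- segs[segs$label %in% c("deletion", "amplification"), , drop = FALSE]
  by_chrom <- split(probe_map, probe_map$chrom)
  calls <- lapply(seq_len(nrow(ab)), function(i) {
    sg <- ab[i, ]
    cm <- by_chrom[[sg$chrom]]
    li <- sg$first_probe; ri <- sg$last_probe
    call <- data.frame(
      strain = attr(segs, "strain") %||% NA_character_,
      chrom = sg$chrom,
      kind = sg$label,
      left_bp_probe = cm$probe_id[li],
      right_bp_probe = cm$probe_id[ri],
      left_index = li,
      right_index = ri,
      start = cm$start[li],
      end = cm$end[ri],
      mean_log2 = sg$mean_log2,
      p_value = sg$p_value,
      n_probes = sg$n_probes,
      length_bp = (cm$start[ri] + cm$end[ri]) / 2 - (cm$start[li] + cm$end[li]) / 2,
      stringsAsFactors = FALSE
    )
    find_flanking_probes(profile, call, params)
  })
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  out <- out[order(match(out$chrom, unique(probe_map$chrom)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("indel_calls", "data.frame")
  out
}

empty_calls <- function() {
  data.frame(
    strain = character(), chrom = character(), kind = character(),
    left_bp_probe = character(), right_bp_probe = character(),
    left_index = integer(), right_index = integer(),
    start = integer(), end = integer(),
    mean_log2 = numeric(), p_value = numeric(), n_probes = integer(),
    length_bp = numeric(),
    left_flank_index = integer(), right_flank_index = integer(),
    left_flank_probe = character(), right_flank_probe = character(),
    stringsAsFactors = FALSE
  )
}

#' Export calls with surrounding probe ratios for manual review
#'
#' Breakpoint fine-tuning is a human judgement in practice; this export
#' lists, for every call, the ratios of the probes inside the call and of
#' up to `n_context` probes on either side so an analyst can audit the
#' automatically chosen breakpoints.
#'
#' @param calls An `indel_calls` table.
#' @param profile The profile the calls came from.
#' @param n_context Probes of context either side.
#' @return Long-format data frame: one row per (call, probe) with the
#'   probe's offset from the call and its ratio.
#' @export
review_export <- function(calls, profile, n_context = 10L) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    x <- profile$log2_ratio[profile$chrom == cl$chrom]
    ids <- profile$probe_id[profile$chrom == cl$chrom]
    idx <- max(1, cl$left_index - n_context):min(length(x), cl$right_index + n_context)
    data.frame(
      call = i, strain = cl$strain, chrom = cl$chrom, kind = cl$kind,
      probe_id = ids[idx], probe_index = idx,
      offset = ifelse(idx < cl$left_index, idx - cl$left_index,
                      ifelse(idx > cl$right_index, idx - cl$right_index, 0L)),
      log2_ratio = x[idx], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
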