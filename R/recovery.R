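#' Score called indels against a planted truth set
#'
#' Matches calls to truth indels per strain, chromosome and kind, where a
#' call matches a truth indel if their probe sets overlap reciprocally by
#' at least 50% (intersection covering at least half of each).  Reports
#' sensitivity over truth indels spanning at least `min_probes` probes
#' (smaller events are below the caller's design resolution), the false
#' discovery proportion over all calls, and the signed probe-index offsets
#' of called vs true boundary probes for every matched pair.
#'
#' @param calls An indel call table from [call_indels()] (rows from several
#'   strains may be combined; a `strain` column is required).
#' @param truth A truth set from [simulate_genealogy_truth()].
#' @param probe_map The probe map both refer to.
#' @param min_probes Minimum truth-indel width (in probes) counted in the
#'   sensitivity denominator.
#' @return List with `sensitivity`, `fdr`, `n_truth`, `n_calls`,
#'   `breakpoint_errors` (data frame with `left_error`, `right_error`),
#'   and `matched_truth`/`matched_calls` logical vectors.
#' @export
truth_recovery_metrics <- function(calls, truth, probe_map, min_probes = 3L) {
  check_probe_map(probe_map)
  by_chrom <- split(probe_map, probe_map$chrom)

  truth_idx <- lapply(seq_len(nrow(truth)), function(i) {
    probes_in_interval(by_chrom[[truth$chrom[i]]], truth$start[i], truth$end[i])
  })
  truth_n <- vapply(truth_idx, length, integer(1))
  eligible <- truth_n >= min_probes

  matched_truth <- rep(FALSE, nrow(truth))
  matched_calls <- rep(FALSE, nrow(calls))
  left_err <- numeric(0)
  right_err <- numeric(0)

  for (ci in seq_len(nrow(calls))) {
    cl <- calls[ci, ]
    cand <- which(truth$strain == cl$strain & truth$chrom == cl$chrom &
                    truth$kind == cl$kind)
    for (ti in cand) {
      tr <- truth_idx[[ti]]
      if (length(tr) == 0) next
      ov <- length(intersect(seq.int(cl$left_index, cl$right_index), tr))
      n_call <- cl$right_index - cl$left_index + 1
      if (ov / n_call >= 0.5 && ov / length(tr) >= 0.5) {
        matched_calls[ci] <- TRUE
        if (!matched_truth[ti]) {
          matched_truth[ti] <- TRUE
          left_err <- c(left_err, cl$left_index - tr[1])
          right_err <- c(right_err, cl$right_index - tr[length(tr)])
        }
      }
    }
  }

  n_truth <- sum(eligible)
  sensitivity <- if (n_truth == 0) NaN else sum(matched_truth & eligible) / n_truth
  fdr <- if (nrow(calls) == 0) NaN else sum(!matched_calls) / nrow(calls)
  list(
    sensitivity = sensitivity,
    fdr = fdr,
    n_truth = n_truth,
    n_calls = nrow(calls),
    breakpoint_errors = data.frame(left_error = left_err, right_error = right_err),
    matched_truth = matched_truth,
    matched_calls = matched_calls
  )
}
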