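#' Plant indels along a strain genealogy
#'
#' Simulates a ground-truth set of deletions and amplifications shared by
#' descent.  Each event originates once on a branch of the supplied strain
#' tree and is inherited by every strain descending from that branch (all
#' carriers share one `locus_id`).  Events are anchored at probe positions,
#' biased towards autosome arms, with lengths drawn from a log-normal
#' distribution.  Optional recombination swaps exchange all loci inside a
#' chromosome interval between two strains, emulating outcrossing.
#'
#' Defaults reflect the structure of natural *C. elegans* indel variation:
#' deletions outnumber amplifications roughly 8:1, ~85% of events fall on
#' autosome arms, and lengths are log-normal with median ~2.7 kb and mean
#' ~8.5 kb.  Events are placed with a minimum separation of
#' `min_gap_probes` probes so that planted loci are individually resolvable
#' on the array (collisions are vanishingly rare at genome scale anyway).
#'
#' @param probe_map A [generate_probe_map()] result.
#' @param tree_spec Strain genealogy: a Newick string or an `ape::phylo`
#'   object whose tip labels are the strain names.
#' @param events_per_branch Number of events originating on each branch:
#'   either a single count applied to every branch or a vector parallel to
#'   the rows of `tree$edge`.
#' @param length_meanlog,length_sdlog Log-normal length parameters (bp).
#' @param arm_bias Probability that an event is anchored on an arm probe.
#' @param deletion_fraction Probability that an event is a deletion (the
#'   complement is an amplification).
#' @param deletion_signal,amplification_signal Expected log2-ratio shift of
#'   probes inside a deletion (must be <= -2) / amplification (>= 1).
#' @param recomb_swaps Optional list of swaps, each a list with elements
#'   `strains` (length-2 character), `chrom`, `start`, `end`; all loci
#'   overlapping the interval have their carrier status exchanged between
#'   the two strains.
#' @param min_gap_probes Minimum number of probes separating two events.
#' @param seed Integer seed.
#'
#' @return A `data.frame` of class `truth_set` with one row per
#'   (strain, locus): columns `strain`, `chrom`, `start`, `end`, `kind`,
#'   `signal_log2`, `locus_id`.  The per-locus table (one row per locus
#'   with its carrier list) is attached as attribute `"loci"` and the tree
#'   as `"tree"`.
#' @export
simulate_genealogy_truth <- function(probe_map,
                                     tree_spec,
                                     events_per_branch = 4,
                                     length_meanlog = log(2700),
                                     length_sdlog = 1.51,
                                     arm_bias = 0.85,
                                     deletion_fraction = 8 / 9,
                                     deletion_signal = -3,
                                     amplification_signal = 1.5,
                                     recomb_swaps = NULL,
                                     min_gap_probes = 10L,
                                     seed = 1L) {
  check_probe_map(probe_map)
  tree <- if (inherits(tree_spec, "phylo")) tree_spec else ape::read.tree(text = tree_spec)
  if (is.null(tree)) stopf("could not parse tree_spec")
  if (anyDuplicated(tree$tip.label)) stopf("strains in tree_spec must be unique")
  if (!(arm_bias >= 0 && arm_bias <= 1)) stopf("arm_bias must lie in [0, 1]")
  if (deletion_signal > -2) stopf("deletion_signal must be <= -2")
  if (amplification_signal < 1) stopf("amplification_signal must be >= 1")

  n_edge <- nrow(tree$edge)
  rates <- if (length(events_per_branch) == 1) {
    rep(as.integer(events_per_branch), n_edge)
  } else if (length(events_per_branch) == n_edge) {
    as.integer(events_per_branch)
  } else {
    stopf("events_per_branch must be a scalar or one count per branch (%d)", n_edge)
  }

  carriers_by_edge <- edge_tip_sets(tree)
  by_chrom <- split(probe_map, probe_map$chrom)
  chrom_names <- names(by_chrom)
  arm_rows <- which(probe_map$region == "arm")
  non_arm_rows <- which(probe_map$region != "arm")
  if (length(arm_rows) == 0) arm_rows <- non_arm_rows
  if (length(non_arm_rows) == 0) non_arm_rows <- arm_rows

  total <- sum(rates)
  loci <- with_seed(seed, {
    occupied <- lapply(chrom_names, function(x) integer(0)) # padded probe indices
    names(occupied) <- chrom_names
    out <- vector("list", total)
    k <- 0L
    for (e in seq_len(n_edge)) {
      for (j in seq_len(rates[e])) {
        k <- k + 1L
        placed <- FALSE
        for (attempt in 1:1000) {
          on_arm <- runif(1) < arm_bias
          pool <- if (on_arm) arm_rows else non_arm_rows
          row <- pool[sample.int(length(pool), 1)]
          chrom <- probe_map$chrom[row]
          start <- probe_map$start[row]
          len <- max(1, round(rlnorm(1, length_meanlog, length_sdlog)))
          cm <- by_chrom[[chrom]]
          end <- min(start + len - 1, cm$end[nrow(cm)])
          idx <- probes_in_interval(cm, start, end)
          if (length(idx) == 0) next
          pad <- seq.int(max(1, idx[1] - min_gap_probes),
                         min(nrow(cm), idx[length(idx)] + min_gap_probes))
          if (any(pad %in% occupied[[chrom]])) next
          occupied[[chrom]] <- c(occupied[[chrom]], pad)
          kind <- if (runif(1) < deletion_fraction) "deletion" else "amplification"
          out[[k]] <- data.frame(
            locus_id = NA_character_, edge = e, chrom = chrom,
            start = start, end = end, kind = kind,
            signal_log2 = if (kind == "deletion") deletion_signal else amplification_signal,
            stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
        if (!placed) stopf("could not place event %d without overlap; genome too crowded", k)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(loci)) {
    loci <- data.frame(locus_id = character(), edge = integer(), chrom = character(),
                       start = integer(), end = integer(), kind = character(),
                       signal_log2 = numeric(), stringsAsFactors = FALSE)
  }
  # genomic order, then assign stable locus ids
  loci <- loci[order(match(loci$chrom, chrom_names), loci$start), , drop = FALSE]
  loci$locus_id <- sprintf("L%04d", seq_len(nrow(loci)))
  loci$carriers <- lapply(loci$edge, function(e) carriers_by_edge[[e]])

  loci$carriers <- apply_recomb_swaps(loci, recomb_swaps, by_chrom)

  truth <- expand_truth(loci)
  attr(truth, "loci") <- loci
  attr(truth, "tree") <- tree
  class(truth) <- c("truth_set", "data.frame")
  truth
}

# tips descending from the child node of each edge
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  # postorder: children before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1]; ch <- edges[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) sort(unique(desc[[tree$edge[r, 2]]])))
}

apply_recomb_swaps <- function(loci, recomb_swaps, by_chrom) {
  carriers <- loci$carriers
  for (sw in recomb_swaps %||% list()) {
    if (!all(c("strains", "chrom", "start", "end") %in% names(sw)) ||
        length(sw$strains) != 2) {
      stopf("each recomb swap needs $strains (length 2), $chrom, $start, $end")
    }
    cm <- by_chrom[[sw$chrom]]
    if (is.null(cm)) stopf("recomb swap chromosome '%s' not in probe map", sw$chrom)
    if (sw$start < 1 || sw$end > max(cm$end) || sw$start > sw$end) {
      stopf("recomb swap interval [%s, %s] outside probe map on %s",
            sw$start, sw$end, sw$chrom)
    }
    hit <- which(loci$chrom == sw$chrom & loci$start <= sw$end & loci$end >= sw$start)
    a <- sw$strains[1]; b <- sw$strains[2]
    for (i in hit) {
      cs <- carriers[[i]]
      has_a <- a %in% cs; has_b <- b %in% cs
      cs <- setdiff(cs, c(a, b))
      if (has_a) cs <- c(cs, b)
      if (has_b) cs <- c(cs, a)
      carriers[[i]] <- sort(cs)
    }
  }
  carriers
}

expand_truth <- function(loci) {
  n_per <- vapply(loci$carriers, length, integer(1))
  keep <- n_per > 0
  truth <- data.frame(
    strain = unlist(loci$carriers[keep]),
    chrom = rep(loci$chrom[keep], n_per[keep]),
    start = rep(loci$start[keep], n_per[keep]),
    end = rep(loci$end[keep], n_per[keep]),
    kind = rep(loci$kind[keep], n_per[keep]),
    signal_log2 = rep(loci$signal_log2[keep], n_per[keep]),
    locus_id = rep(loci$locus_id[keep], n_per[keep]),
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  truth
}

# indices (within one chromosome's probe table) of probes overlapping
# [start, end]; assumes cm sorted by start with non-overlapping probes
probes_in_interval <- function(cm, start, end) {
  first <- findInterval(start - 1L, cm$end) + 1L
  last <- findInterval(end, cm$start)
  if (first > last) integer(0) else seq.int(first, last)
}
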