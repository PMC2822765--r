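#' Match indel alleles across strains into loci
#'
#' Two calls of the same kind on the same chromosome carry the same allele
#' if they overlap and both their left and right breakpoint probes are
#' within `tolerance_probes` probes of each other, or if both breakpoint
#' probes of one call fall within the region spanned by the other call's
#' flanking probes (the relaxed rule for calls whose breakpoints are less
#' certain).  Loci are the connected components (transitive closure) of
#' this match relation; a locus's canonical breakpoints are the modal
#' breakpoint probes among its members.
#'
#' @param calls Combined `indel_calls` from all strains (one probe map).
#' @param probe_map The probe map the calls refer to.
#' @param tolerance_probes Breakpoint tolerance in probe-index units.
#' @return A `data.frame` of class `indel_loci` in genomic order:
#'   `locus_id`, `kind`, `chrom`, canonical `left_index`/`right_index` and
#'   probe ids, `start`/`end` (bp span of the canonical breakpoint
#'   probes), `n_carriers`, and list columns `carriers` (strain labels)
#'   and `members` (row indices into `calls`).  Chains that transitively
#'   join calls farther apart than the tolerance are reported in the
#'   `chained` attribute.
#' @export
match_indel_alleles <- function(calls, probe_map, tolerance_probes = 3L) {
  check_probe_map(probe_map)
  n <- nrow(calls)
  if (n == 0) {
    out <- data.frame(locus_id = character(), kind = character(),
                      chrom = character(), left_index = integer(),
                      right_index = integer(), left_bp_probe = character(),
                      right_bp_probe = character(), start = integer(),
                      end = integer(), n_carriers = integer(),
                      stringsAsFactors = FALSE)
    out$carriers <- list()
    out$members <- list()
    class(out) <- c("indel_loci", "data.frame")
    return(out)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }

  chrom_sizes <- tapply(probe_map$index, probe_map$chrom, max)
  lf <- ifelse(is.na(calls$left_flank_index), 1L, calls$left_flank_index)
  rf <- ifelse(is.na(calls$right_flank_index),
               as.integer(chrom_sizes[calls$chrom]), calls$right_flank_index)

  groups <- split(seq_len(n), paste(calls$chrom, calls$kind))
  for (g in groups) {
    if (length(g) < 2) next
    for (a in seq_along(g)[-length(g)]) {
      for (b in (a + 1):length(g)) {
        i <- g[a]; j <- g[b]
        overlaps <- calls$start[i] <= calls$end[j] && calls$end[i] >= calls$start[j]
        close_bp <- overlaps &&
          abs(calls$left_index[i] - calls$left_index[j]) <= tolerance_probes &&
          abs(calls$right_index[i] - calls$right_index[j]) <= tolerance_probes
        in_flanks <- (calls$left_index[i] >= lf[j] && calls$right_index[i] <= rf[j]) ||
          (calls$left_index[j] >= lf[i] && calls$right_index[j] <= rf[i])
        if (close_bp || in_flanks) union_(i, j)
      }
    }
  }

  comp <- vapply(seq_len(n), find, integer(1))
  members <- split(seq_len(n), comp)
  loci <- lapply(members, function(m) {
    li <- modal_value(calls$left_index[m])
    ri <- modal_value(calls$right_index[m])
    cm <- probe_map[probe_map$chrom == calls$chrom[m[1]], , drop = FALSE]
    data.frame(
      kind = calls$kind[m[1]],
      chrom = calls$chrom[m[1]],
      left_index = li,
      right_index = ri,
      left_bp_probe = cm$probe_id[li],
      right_bp_probe = cm$probe_id[ri],
      start = cm$start[li],
      end = cm$end[ri],
      n_carriers = length(unique(calls$strain[m])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, loci)
  out$carriers <- lapply(members, function(m) sort(unique(calls$strain[m])))
  out$members <- members
  ord <- order(match(out$chrom, unique(probe_map$chrom)), out$start)
  out <- out[ord, , drop = FALSE]
  out$locus_id <- sprintf("locus%04d", seq_len(nrow(out)))
  out <- out[, c("locus_id", "kind", "chrom", "left_index", "right_index",
                 "left_bp_probe", "right_bp_probe", "start", "end",
                 "n_carriers", "carriers", "members")]
  rownames(out) <- NULL

  # note members whose breakpoints ended up farther apart than the
  # tolerance (joined through a chain or the flank rule)
  chained <- vapply(seq_len(nrow(out)), function(k) {
    m <- out$members[[k]]
    max(diff(range(calls$left_index[m])), diff(range(calls$right_index[m]))) >
      tolerance_probes
  }, logical(1))
  attr(out, "chained") <- out$locus_id[chained]
  class(out) <- c("indel_loci", "data.frame")
  out
}

#' Build the strain-by-locus presence/absence matrix
#'
#' Deletion loci are treated as discrete presence/absence characters;
#' amplifications are excluded by default because they are less robustly
#' detected (and their true genomic position is unknown).
#'
#' @param loci An `indel_loci` table.
#' @param strains Strain labels defining the row order.  The reference
#'   strain must not be included: ratios are isolate/reference, so the
#'   reference carries no markers by construction.
#' @param kinds Locus kinds to include.
#' @return Binary integer matrix, rows = strains, columns = loci in
#'   genomic order (column names are locus ids).
#' @export
build_presence_absence <- function(loci, strains, kinds = "deletion") {
  sel <- loci[loci$kind %in% kinds, , drop = FALSE]
  mat <- matrix(0L, nrow = length(strains), ncol = nrow(sel),
                dimnames = list(strains, sel$locus_id))
  for (k in seq_len(nrow(sel))) {
    carriers <- intersect(sel$carriers[[k]], strains)
    mat[carriers, k] <- 1L
  }
  mat
}

calls_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Genes affected by an indel
#'
#' The affected span runs from the start of the left breakpoint probe to
#' the end of the right breakpoint probe.  Genes intersecting the span are
#' returned; a gene completely contained in the span is wholly affected,
#' any other intersecting gene partially.
#'
#' @param x A single-row call or locus (needs `chrom`, `start`, `end`).
#' @param genes Gene table: `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `biotype` (`gene` or `pseudogene`).
#' @return Data frame `gene_id`, `effect` (`wholly`/`partially`),
#'   `biotype`.
#' @export
annotate_genes <- function(x, genes) {
  hits <- GenomicRanges::findOverlaps(calls_to_granges(x), calls_to_granges(genes))
  gi <- S4Vectors::subjectHits(hits)
  xi <- S4Vectors::queryHits(hits)
  wholly <- genes$start[gi] >= x$start[xi] & genes$end[gi] <= x$end[xi]
  data.frame(
    row = xi,
    gene_id = genes$gene_id[gi],
    effect = ifelse(wholly, "wholly", "partially"),
    biotype = genes$biotype[gi],
    stringsAsFactors = FALSE
  )
}

#' Assign a genomic region (arm, center or X) to calls
#'
#' Region of the midpoint of the call's left breakpoint probe: inside an
#' arm interval it is `arm`, on the X chromosome always `X`, otherwise
#' `center`.
#'
#' @param calls An `indel_calls` table (or any table with `chrom` and
#'   `left_index`).
#' @param boundaries Arm intervals: `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [arm_boundaries()].
#' @param probe_map Probe map used to resolve the left breakpoint probe's
#'   midpoint.
#' @param x_chromosome Chromosome label always assigned `X`.
#' @return Character vector of regions, one per call.
#' @export
assign_region <- function(calls, boundaries, probe_map, x_chromosome = "X") {
  check_probe_map(probe_map)
  by_chrom <- split(probe_map, probe_map$chrom)
  vapply(seq_len(nrow(calls)), function(i) {
    if (calls$chrom[i] == x_chromosome) return("X")
    cm <- by_chrom[[calls$chrom[i]]]
    mid <- (cm$start[calls$left_index[i]] + cm$end[calls$left_index[i]]) / 2
    b <- boundaries[boundaries$chrom == calls$chrom[i], , drop = FALSE]
    if (any(mid >= b$start & mid <= b$end)) "arm" else "center"
  }, character(1))
}

#' Catalog summary tables
#'
#' Builds the descriptive summaries of an indel catalog: per-strain counts
#' and length statistics (indels found in multiple strains counted once
#' per strain), per-strain deleted gene and pseudogene counts when a gene
#' table is supplied, the pairwise shared-deletion matrix (diagonal =
#' per-strain deletion locus counts), the sharing spectrum (for each
#' strain, how many other strains carry each of its deletions), and the
#' overall number of distinguishable loci.
#'
#' @param calls Combined `indel_calls` for all strains.
#' @param loci Matching `indel_loci`.
#' @param strains Strain labels (reference excluded).
#' @param genes Optional gene table for affected-gene counts.
#' @return List with `per_strain`, `pairwise_shared`, `sharing_spectrum`,
#'   `n_loci` (per kind) and, when genes are given, `affected_genes`.
#' @export
summarize_catalog <- function(calls, loci, strains, genes = NULL) {
  per_strain <- do.call(rbind, lapply(strains, function(s) {
    cs <- calls[calls$strain == s, , drop = FALSE]
    data.frame(
      strain = s,
      deletions = sum(cs$kind == "deletion"),
      amplifications = sum(cs$kind == "amplification"),
      median_length = if (nrow(cs)) median(cs$length_bp) else NA_real_,
      mean_length = if (nrow(cs)) mean(cs$length_bp) else NA_real_,
      max_length = if (nrow(cs)) max(cs$length_bp) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))

  del <- loci[loci$kind == "deletion", , drop = FALSE]
  ns <- length(strains)
  shared <- matrix(0L, ns, ns, dimnames = list(strains, strains))
  for (k in seq_len(nrow(del))) {
    carriers <- intersect(del$carriers[[k]], strains)
    shared[carriers, carriers] <- shared[carriers, carriers] + 1L
  }

  spectrum <- lapply(strains, function(s) {
    mine <- del[vapply(del$carriers, function(cs) s %in% cs, logical(1)), ,
                drop = FALSE]
    n_others <- vapply(mine$carriers, function(cs) length(intersect(cs, strains)) - 1L,
                       integer(1))
    table(factor(n_others, levels = 0:(ns - 1)))
  })
  names(spectrum) <- strains

  out <- list(
    per_strain = per_strain,
    pairwise_shared = shared,
    sharing_spectrum = spectrum,
    n_loci = table(loci$kind)
  )

  if (!is.null(genes)) {
    ann <- annotate_genes(del, genes)
    gene_counts <- do.call(rbind, lapply(strains, function(s) {
      keep <- vapply(del$carriers, function(cs) s %in% cs, logical(1))
      rows <- which(keep)
      g <- ann[ann$row %in% rows, , drop = FALSE]
      data.frame(
        strain = s,
        deleted_genes = length(unique(g$gene_id[g$biotype == "gene"])),
        deleted_pseudogenes = length(unique(g$gene_id[g$biotype == "pseudogene"])),
        stringsAsFactors = FALSE
      )
    }))
    out$affected_genes <- gene_counts
    out$per_strain <- merge(per_strain, gene_counts, by = "strain", sort = FALSE)
  }
  out
}

#' Chromosome, strain and region tests on the indel catalog
#'
#' Reproduces the catalog's statistical battery: (a) chi-square
#' goodness-of-fit of per-chromosome deletion and amplification counts
#' against expectations proportional to the share of probes targeting each
#' chromosome (correcting for chromosome length and gene content); (b)
#' one-way ANOVA of raw indel lengths by strain and by chromosome; (c)
#' Welch's two-sample t-test comparing indel lengths on autosome arms
#' against centers plus the X chromosome.  Lengths are
#' midpoint-to-midpoint and indels found in multiple strains are counted
#' multiple times.  Raw P values are reported without multiple-testing
#' correction.
#'
#' @param calls Combined `indel_calls`.
#' @param probe_map The probe map (defines probe shares per chromosome).
#' @param boundaries Arm intervals for [assign_region()].
#' @param x_chromosome X chromosome label.
#' @return List of `htest`/`anova` results: `chisq_deletion`,
#'   `chisq_amplification`, `anova_strain`, `anova_chromosome`,
#'   `ttest_arm_vs_center`.
#' @export
run_length_and_count_tests <- function(calls, probe_map, boundaries,
                                       x_chromosome = "X") {
  check_probe_map(probe_map)
  chroms <- unique(probe_map$chrom)
  shares <- as.numeric(table(factor(probe_map$chrom, levels = chroms)))
  shares <- shares / sum(shares)

  chisq_for <- function(kind) {
    obs <- as.numeric(table(factor(calls$chrom[calls$kind == kind],
                                   levels = chroms)))
    if (sum(obs) == 0 || length(chroms) < 2) return(NULL)
    suppressWarnings(chisq.test(obs, p = shares))
  }

  anova_for <- function(group) {
    tab <- table(group)
    small <- names(tab)[tab < 2]
    if (length(small)) {
      warnf("dropping groups with < 2 indels from ANOVA: %s",
            paste(small, collapse = ", "))
    }
    keep <- !(group %in% small)
    if (length(unique(group[keep])) < 2) return(NULL)
    summary(aov(calls$length_bp[keep] ~ factor(group[keep])))
  }

  region <- assign_region(calls, boundaries, probe_map, x_chromosome)
  arm_lengths <- calls$length_bp[region == "arm"]
  other_lengths <- calls$length_bp[region != "arm"]
  ttest <- if (length(arm_lengths) >= 2 && length(other_lengths) >= 2) {
    t.test(arm_lengths, other_lengths) # Welch by default
  } else {
    NULL
  }

  list(
    chisq_deletion = chisq_for("deletion"),
    chisq_amplification = chisq_for("amplification"),
    anova_strain = anova_for(calls$strain),
    anova_chromosome = anova_for(calls$chrom),
    ttest_arm_vs_center = ttest,
    region = region
  )
}
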