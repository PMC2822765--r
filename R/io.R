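# Readers and writers for the on-disk formats the pipeline touches.
#
# Coordinate dialects: GFF3 and the ratio/probe tables are 1-based
# inclusive (the internal convention); BED is 0-based half-open.  Writers
# are deterministic given identical inputs: no timestamps inside data
# files.

atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not write %s", path)
  invisible(path)
}

num_chr <- function(x) sprintf("%.17g", x)

#' Read a per-strain probe ratio table
#'
#' Canonical pipeline input: a TSV with header columns `probe_id`,
#' `chrom`, `start`, `end`, `test_intensity`, `ref_intensity` and
#' optionally `log2_ratio` (computed as `log2(test/ref)` when absent).
#' Rows out of (chrom, start) order are sorted with a warning; duplicate
#' probe ids and non-numeric intensities are errors naming the offending
#' id / line.
#'
#' @param path File path.
#' @param strain Strain label to record on the profile (defaults to the
#'   file name).
#' @param normalized Whether the ratios in the file are already
#'   normalized.
#' @return A `ratio_profile`.
#' @export
read_ratio_table <- function(path, strain = NULL,
                             normalized = FALSE) {
  raw <- read.delim(path, colClasses = "character", comment.char = "#",
                    check.names = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "test_intensity", "ref_intensity")
  if (!all(need %in% names(raw))) {
    stopf("ratio table %s lacks columns: %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  dup <- raw$probe_id[duplicated(raw$probe_id)]
  if (length(dup)) stopf("duplicate probe id in %s: %s", path, dup[1])

  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stopf("non-numeric %s at line %d of %s: '%s'", col, bad[1] + 1L, path,
            raw[[col]][bad[1]])
    }
    v
  }
  df <- data.frame(
    probe_id = raw$probe_id,
    chrom = raw$chrom,
    start = as.integer(to_num("start")),
    end = as.integer(to_num("end")),
    test_intensity = to_num("test_intensity"),
    ref_intensity = to_num("ref_intensity"),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 1 | df$end < df$start)) {
    stopf("invalid 1-based coordinates in %s", path)
  }
  df$log2_ratio <- if ("log2_ratio" %in% names(raw)) {
    to_num("log2_ratio")
  } else {
    log2(df$test_intensity / df$ref_intensity)
  }
  ord <- order(match(df$chrom, unique(df$chrom)), df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warnf("%s is not sorted by (chrom, start); sorting", path)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  new_ratio_profile(df, strain = strain %||% sub("\\.[^.]*$", "", basename(path)),
                    normalized = normalized)
}

#' Write a ratio profile as the pipeline's TSV
#' @param profile A `ratio_profile`.
#' @param path Output path.
#' @export
write_ratio_table <- function(profile, path) {
  atomically(path, function(tmp) {
    df <- as.data.frame(profile)[, c("probe_id", "chrom", "start", "end",
                                     "test_intensity", "ref_intensity",
                                     "log2_ratio")]
    df$test_intensity <- num_chr(df$test_intensity)
    df$ref_intensity <- num_chr(df$ref_intensity)
    df$log2_ratio <- num_chr(df$log2_ratio)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write / read a probe map as BED-like TSV
#'
#' On disk the map is 0-based half-open (`chrom`, `start`, `end`,
#' `probe_id`, `region`); in memory it is 1-based inclusive.
#'
#' @param probe_map A probe map.
#' @param path File path.
#' @export
write_probe_map <- function(probe_map, path) {
  atomically(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("# probe map; columns: chrom start(0-based) end probe_id region", con)
    write.table(
      data.frame(probe_map$chrom, probe_map$start - 1L, probe_map$end,
                 probe_map$probe_id, probe_map$region),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  })
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "probe_id", "region"),
                   stringsAsFactors = FALSE)
  df$start <- df$start + 1L
  out <- lapply(split(df, df$chrom), function(cm) {
    cm <- cm[order(cm$start), , drop = FALSE]
    cm$index <- seq_len(nrow(cm))
    cm
  })
  out <- do.call(rbind, out[unique(df$chrom)])
  out <- out[, c("probe_id", "chrom", "start", "end", "region", "index")]
  rownames(out) <- NULL
  class(out) <- c("probe_map", "data.frame")
  out
}

calls_gff_cols <- c("strain", "mean_log2", "p_value", "n_probes",
                    "left_bp_probe", "right_bp_probe",
                    "left_index", "right_index",
                    "left_flank_probe", "right_flank_probe",
                    "left_flank_index", "right_flank_index", "length_bp")

#' Write / read indel calls as GFF3
#'
#' One feature per call (`source=cgh-indel`, `type` deletion or
#' amplification, 1-based inclusive coordinates spanning the breakpoint
#' probes) with all call fields carried as attributes at full double
#' precision, so `read_calls_gff3(write_calls_gff3(x)) == x`
#' field-for-field.
#'
#' @param calls An `indel_calls` table.
#' @param path File path.
#' @export
write_calls_gff3 <- function(calls, path) {
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
  S4Vectors::mcols(gr)$source <- "cgh-indel"
  S4Vectors::mcols(gr)$type <- calls$kind
  for (col in calls_gff_cols) {
    v <- calls[[col]]
    v <- if (is.numeric(v)) ifelse(is.na(v), ".", num_chr(v)) else ifelse(is.na(v), ".", v)
    S4Vectors::mcols(gr)[[col]] <- v
  }
  atomically(path, function(tmp) {
    rtracklayer::export(gr, tmp, format = "gff3")
  })
}

#' @rdname write_calls_gff3
#' @export
read_calls_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 %s: %s", path,
                                           conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  missing <- setdiff(calls_gff_cols, names(mc))
  if (length(missing)) {
    stopf("GFF3 %s lacks call attributes: %s", path,
          paste(missing, collapse = ", "))
  }
  undot <- function(v) ifelse(v == ".", NA, v)
  out <- data.frame(
    strain = as.character(mc$strain),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    kind = as.character(mc$type),
    left_bp_probe = as.character(mc$left_bp_probe),
    right_bp_probe = as.character(mc$right_bp_probe),
    left_index = as.integer(mc$left_index),
    right_index = as.integer(mc$right_index),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    mean_log2 = as.numeric(mc$mean_log2),
    p_value = as.numeric(mc$p_value),
    n_probes = as.integer(mc$n_probes),
    length_bp = as.numeric(mc$length_bp),
    left_flank_index = as.integer(undot(mc$left_flank_index)),
    right_flank_index = as.integer(undot(mc$right_flank_index)),
    left_flank_probe = as.character(undot(mc$left_flank_probe)),
    right_flank_probe = as.character(undot(mc$right_flank_probe)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("indel_calls", "data.frame")
  out
}

#' Export calls as BED (0-based half-open)
#'
#' The BED span runs from the left breakpoint probe's start to the right
#' breakpoint probe's end; the name field is `strain:kind`.
#'
#' @param calls An `indel_calls` table.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
  S4Vectors::mcols(gr)$name <- paste0(calls$strain, ":", calls$kind)
  atomically(path, function(tmp) {
    rtracklayer::export(gr, tmp, format = "bed")
  })
}

#' Write a truth set as GFF3
#' @param truth A `truth_set`.
#' @param path Output path.
#' @export
write_truth_gff3 <- function(truth, path) {
  gr <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end))
  S4Vectors::mcols(gr)$source <- "cgh-sim"
  S4Vectors::mcols(gr)$type <- truth$kind
  S4Vectors::mcols(gr)$strain <- truth$strain
  S4Vectors::mcols(gr)$locus_id <- truth$locus_id
  S4Vectors::mcols(gr)$signal <- num_chr(truth$signal_log2)
  atomically(path, function(tmp) rtracklayer::export(gr, tmp, format = "gff3"))
}

#' Read gene annotations from GFF3
#'
#' Keeps features whose type is `gene` or `pseudogene` (the type doubles
#' as the biotype).
#'
#' @param path GFF3 path.
#' @return Gene table for [annotate_genes()].
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("gene", "pseudogene")]
  ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$gene_id
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = as.character(S4Vectors::mcols(gr)$type),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations as GFF3
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  S4Vectors::mcols(gr)$source <- "cgh-sim"
  S4Vectors::mcols(gr)$type <- genes$biotype
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  atomically(path, function(tmp) rtracklayer::export(gr, tmp, format = "gff3"))
}

#' Read / write arm boundary intervals as BED
#' @param boundaries Data frame `chrom`, `start`, `end` (1-based).
#' @param path File path.
#' @export
write_boundaries_bed <- function(boundaries, path) {
  gr <- GenomicRanges::GRanges(boundaries$chrom,
                               IRanges::IRanges(boundaries$start, boundaries$end))
  atomically(path, function(tmp) rtracklayer::export(gr, tmp, format = "bed"))
}

#' @rdname write_boundaries_bed
#' @export
read_boundaries_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write / read the presence/absence matrix as TSV
#'
#' Rows are strains, columns loci; the header row carries locus ids and
#' the first column the strain labels.
#'
#' @param mat Binary matrix.
#' @param path File path.
#' @export
write_pa_matrix <- function(mat, path) {
  atomically(path, function(tmp) {
    df <- data.frame(strain = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) stopf("matrix %s has non-binary cells", path)
  mat
}

#' Write a tree as Newick
#'
#' Internal node labels (e.g. bootstrap support, or combined
#' `"CS%/W%"` figures) are written as-is; leaf names containing
#' whitespace or Newick metacharacters are single-quoted.  Unrooted trees
#' keep their trifurcating base.
#'
#' @param tree An `ape::phylo` (or [bootstrap_consensus()] result).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "bootstrap_consensus")) tree <- tree$tree
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  quote_label <- function(lab) {
    if (grepl("[[:space:](),:;]", lab)) paste0("'", lab, "'") else lab
  }
  node_label <- function(node) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - ntip]
    if (is.na(lab)) "" else lab
  }
  serialize <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], serialize, character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_label(node))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  atomically(path, function(tmp) {
    writeLines(paste0(serialize(root), ";"), tmp)
  })
}

#' Thin importer for GEO series-matrix-style files
#'
#' Parses the `!series_matrix_table_begin` / `_end` block of a
#' series-matrix file whose first column is the probe id and whose sample
#' columns hold log2 ratios, and aligns the values to a probe map.  The
#' canonical pipeline input remains the documented ratio TSV; profiles
#' read this way carry ratios only (no intensities), so normalization is
#' skipped for them.
#'
#' @param path Series-matrix file.
#' @param probe_map Probe map supplying probe coordinates.
#' @return Named list of `ratio_profile`s (one per sample column).
#' @export
read_series_matrix <- function(path, probe_map) {
  lines <- readLines(path)
  from <- grep("^!series_matrix_table_begin", lines)
  to <- grep("^!series_matrix_table_end", lines)
  if (length(from) != 1 || length(to) != 1 || to <= from + 1) {
    stopf("%s has no series matrix table block", path)
  }
  tab <- read.delim(text = lines[(from + 1):(to - 1)], check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  keep <- match(probe_map$probe_id, ids)
  if (anyNA(keep)) {
    stopf("%d probe map probes missing from %s", sum(is.na(keep)), path)
  }
  samples <- names(tab)[-1]
  out <- lapply(samples, function(s) {
    df <- data.frame(
      probe_id = probe_map$probe_id,
      chrom = probe_map$chrom,
      start = probe_map$start,
      end = probe_map$end,
      test_intensity = NA_real_,
      ref_intensity = NA_real_,
      log2_ratio = as.numeric(tab[[s]][keep]),
      stringsAsFactors = FALSE
    )
    new_ratio_profile(df, strain = s, normalized = TRUE)
  })
  names(out) <- samples
  out
}
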