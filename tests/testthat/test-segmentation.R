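test_that("identical values always merge into one segment per chromosome", {
  prof <- manual_profile(rep(0, 50))
  prof2 <- manual_profile(rep(0, 30), chrom = "c2")
  both <- rbind(prof, prof2)
  attr(both, "normalized") <- TRUE
  class(both) <- class(prof)
  segs <- segment_profile(both, 0.05)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$n_probes, c(50L, 30L))
})

test_that("a planted change region is recovered exactly and matches the least-squares oracle", {
  set.seed(1)
  x <- rnorm(20, 0, 0.2)
  x[8:12] <- x[8:12] - 3
  segs <- segment_profile(manual_profile(x), 0.05)
  expect_identical(nrow(segs), 3L)
  expect_identical(segs$first_probe, c(1L, 8L, 13L))
  expect_identical(segs$last_probe, c(7L, 12L, 20L))
  o <- ls_changepoint3(x)
  expect_identical(c(segs$first_probe[2], segs$last_probe[2]), o)
  # segment means are the arithmetic means of member ratios
  expect_equal(segs$mean_log2[2], mean(x[8:12]), tolerance = 1e-12)
})

test_that("the default merge threshold is 0.05", {
  expect_identical(formals(segment_profile)$merge_alpha, 0.05)
  expect_identical(calling_params()$merge_alpha, 0.05)
})

test_that("the lazy heap reproduces an eager re-scan of all adjacent pairs", {
  set.seed(31)
  for (r in 1:12) {
    x <- rnorm(60, 0, 0.25)
    if (r %% 2 == 0) x[20:26] <- x[20:26] - 3
    if (r %% 3 == 0) x[40:44] <- x[40:44] + 1.5
    gsd <- median(abs(diff(x))) / (sqrt(2) * qnorm(0.75))
    ref <- eager_segment(x, 0.05, gsd)
    segs <- segment_profile(manual_profile(x), 0.05)
    expect_identical(segs$first_probe, as.integer(ref[, 1]))
    expect_identical(segs$last_probe, as.integer(ref[, 2]))
  }
})

test_that("segments partition each chromosome without gaps or overlaps", {
  set.seed(7)
  for (r in 1:10) {
    x <- rnorm(80, 0, 0.3)
    segs <- segment_profile(manual_profile(x), 0.05)
    expect_identical(segs$first_probe[1], 1L)
    expect_identical(segs$last_probe[nrow(segs)], 80L)
    if (nrow(segs) > 1) {
      expect_identical(segs$first_probe[-1], segs$last_probe[-nrow(segs)] + 1L)
    }
    cl <- classify_and_filter(segs)
    expect_identical(cl$first_probe[1], 1L)
    expect_identical(cl$last_probe[nrow(cl)], 80L)
    if (nrow(cl) > 1) {
      expect_identical(cl$first_probe[-1], cl$last_probe[-nrow(cl)] + 1L)
    }
  }
})

test_that("chromosomes with fewer than 2 probes form a single segment", {
  prof <- manual_profile(c(-1.3))
  segs <- segment_profile(prof, 0.05)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_probes, 1L)
})

test_that("classification applies the mean and P cutoffs and the 2-probe deletion exception", {
  set.seed(5)
  # an aberrant segment: mean -2.5 over 5 probes
  x1 <- rnorm(30, 0, 0.15)
  x1[10:14] <- x1[10:14] - 2.5
  cl1 <- classify_and_filter(segment_profile(manual_profile(x1)))
  del <- cl1[cl1$label == "deletion", ]
  expect_identical(nrow(del), 1L)
  expect_identical(c(del$first_probe, del$last_probe), c(10L, 14L))
  expect_lte(del$p_value, 0.01)
  expect_lte(del$mean_log2, -2)

  # 2-probe candidate with both ratios <= -2 is kept despite df = 1
  x2 <- rnorm(30, 0, 0.15)
  x2[15:16] <- c(-2.4, -2.6)
  cl2 <- classify_and_filter(segment_profile(manual_profile(x2)))
  del2 <- cl2[cl2$label == "deletion", ]
  expect_identical(nrow(del2), 1L)
  expect_identical(c(del2$first_probe, del2$last_probe), c(15L, 16L))

  # flat segments stay normal
  cl3 <- classify_and_filter(segment_profile(manual_profile(rep(0, 25))))
  expect_identical(unique(cl3$label), "normal")

  # aberrant but too short (and not the 2-probe exception) is relabeled
  x4 <- rnorm(30, 0, 0.1)
  x4[12:13] <- c(-1.6, -2.1) # mean < -1.8 but not both <= -2
  cl4 <- classify_and_filter(segment_profile(manual_profile(x4)),
                             calling_params(deletion_cutoff = -1.5))
  expect_false(any(cl4$label == "deletion"))
})

test_that("flanking probes mark where normal ratios consistently reappear", {
  # immediate neighbors at 0: flanks adjacent to the breakpoints
  x <- c(rep(0, 7), rep(-3, 5), rep(0, 8))
  prof <- manual_profile(x)
  calls <- call_indels(prof, probe_map_for(prof))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$left_flank_index, 7L)
  expect_identical(calls$right_flank_index, 13L)

  # shoulder outward from the right breakpoint: -2.9 | -1.1 -0.6 0.1 0 ...
  x2 <- c(rep(0, 6), rep(-3, 4), -2.9, -1.1, -0.6, 0.1, rep(0, 6))
  prof2 <- manual_profile(x2)
  calls2 <- call_indels(prof2, probe_map_for(prof2))
  expect_identical(nrow(calls2), 1L)
  expect_identical(calls2$right_index, 11L) # breakpoint at the -2.9 probe
  expect_identical(calls2$right_flank_index, 13L) # the -0.6 probe

  # amplification: 0.7 fails the < 0.5 rule, 0.1 passes
  x3 <- c(rep(0, 6), rep(1.6, 4), 0.7, 0.1, rep(0, 8))
  prof3 <- manual_profile(x3)
  calls3 <- call_indels(prof3, probe_map_for(prof3))
  amp <- calls3[calls3$kind == "amplification", ]
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$right_flank_index, 12L) # the 0.1 probe
  expect_identical(amp$left_flank_index, 6L)

  # flanks absent when the chromosome ends inside the aberration
  x4 <- c(rep(-3, 5), rep(0, 10))
  prof4 <- manual_profile(x4)
  calls4 <- call_indels(prof4, probe_map_for(prof4))
  expect_true(is.na(calls4$left_flank_index))
  expect_identical(calls4$right_flank_index, 6L)
})

test_that("indel length runs from breakpoint probe middle to middle", {
  # probes [1000,1050] and [3400,3450]: midpoints 1025 and 3425
  df <- data.frame(
    probe_id = sprintf("Pc1_%06d", 1:8),
    chrom = "c1",
    start = c(100, 400, 700, 1000, 3400, 3700, 4000, 4300),
    end = c(150, 450, 750, 1050, 3450, 3750, 4050, 4350),
    test_intensity = 4096, ref_intensity = 4096,
    log2_ratio = c(0, 0, 0, -3, -3, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  attr(df, "strain") <- "s1"
  attr(df, "normalized") <- TRUE
  class(df) <- c("ratio_profile", "data.frame")
  calls <- call_indels(df, probe_map_for(df))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length_bp, 3425 - 1025)
})

test_that("calls are invariant to chromosome processing order", {
  set.seed(44)
  x1 <- rnorm(40, 0, 0.2); x1[10:14] <- x1[10:14] - 3
  x2 <- rnorm(40, 0, 0.2); x2[20:25] <- x2[20:25] + 1.5
  p12 <- rbind(manual_profile(x1, chrom = "c1"), manual_profile(x2, chrom = "c2"))
  p21 <- rbind(manual_profile(x2, chrom = "c2"), manual_profile(x1, chrom = "c1"))
  attr(p12, "normalized") <- TRUE; attr(p12, "strain") <- "s1"
  attr(p21, "normalized") <- TRUE; attr(p21, "strain") <- "s1"
  class(p12) <- class(p21) <- c("ratio_profile", "data.frame")
  c12 <- call_indels(p12, probe_map_for(p12))
  c21 <- call_indels(p21, probe_map_for(p21))
  key <- function(cl) {
    o <- order(cl$chrom, cl$start)
    cl2 <- cl[o, ]; rownames(cl2) <- NULL; cl2
  }
  expect_identical(key(c12), key(c21))
})

test_that("lowering the amplification cutoff only adds calls", {
  set.seed(55)
  x <- rnorm(120, 0, 0.2)
  x[10:14] <- x[10:14] + 0.9   # below the 1.0 cutoff
  x[40:45] <- x[40:45] + 1.5   # solidly above
  x[80:84] <- x[80:84] - 3
  prof <- manual_profile(x)
  pm <- probe_map_for(prof)
  strict <- call_indels(prof, pm, calling_params(amplification_cutoff = 1.0))
  relaxed <- call_indels(prof, pm, calling_params(amplification_cutoff = 0.8))
  strict_amp <- strict[strict$kind == "amplification", ]
  relaxed_amp <- relaxed[relaxed$kind == "amplification", ]
  expect_gte(nrow(relaxed_amp), nrow(strict_amp))
  for (i in seq_len(nrow(strict_amp))) {
    expect_true(any(relaxed_amp$left_index == strict_amp$left_index[i] &
                      relaxed_amp$right_index == strict_amp$right_index[i]))
  }
  # deletions unaffected
  unrowname <- function(d) { rownames(d) <- NULL; d }
  expect_identical(unrowname(strict[strict$kind == "deletion", ]),
                   unrowname(relaxed[relaxed$kind == "deletion", ]))
})

test_that("noise-free planted indels are recovered exactly at small scale", {
  pm <- generate_probe_map(tiny_layout(len = 3e5), seed = 23)
  truth <- simulate_genealogy_truth(pm, "(A,B,C,D);", events_per_branch = 4,
                                    length_meanlog = log(2000),
                                    length_sdlog = 0.4, seed = 29)
  for (s in c("A", "C")) {
    ts <- truth[truth$strain == s, , drop = FALSE]
    prof <- simulate_ratio_profile(pm, ts, noise_config(0, 0, seed = 1),
                                   strain = s)
    attr(prof, "normalized") <- TRUE
    calls <- call_indels(prof, pm)
    rec <- truth_recovery_metrics(calls, ts, pm)
    expect_identical(rec$fdr, 0)
    expect_identical(rec$sensitivity, 1)
    expect_true(all(rec$breakpoint_errors == 0))
  }
})
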