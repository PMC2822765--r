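pm_cat <- generate_probe_map(tiny_layout(len = 3e5), seed = 19)

test_that("allele matching applies the 3-probe breakpoint rule", {
  # identical breakpoints: one locus
  calls <- bind_calls(manual_call(pm_cat, "I", 100, 110, strain = "A"),
                      manual_call(pm_cat, "I", 100, 110, strain = "B"))
  loci <- match_indel_alleles(calls, pm_cat)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$carriers[[1]], c("A", "B"))
  expect_identical(loci$n_carriers, 2L)

  # left 3 apart, right 2 apart, overlapping: still one locus
  calls2 <- bind_calls(manual_call(pm_cat, "I", 100, 110, strain = "A"),
                       manual_call(pm_cat, "I", 103, 112, strain = "B"))
  expect_identical(nrow(match_indel_alleles(calls2, pm_cat)), 1L)

  # left 4 apart with tight flanks: two loci
  calls3 <- bind_calls(
    manual_call(pm_cat, "I", 100, 110, strain = "A",
                left_flank = 99, right_flank = 111),
    manual_call(pm_cat, "I", 104, 112, strain = "B",
                left_flank = 103, right_flank = 113))
  expect_identical(nrow(match_indel_alleles(calls3, pm_cat)), 2L)

  # but breakpoints inside the other call's flank span do match
  calls4 <- bind_calls(
    manual_call(pm_cat, "I", 100, 110, strain = "A",
                left_flank = 95, right_flank = 115),
    manual_call(pm_cat, "I", 104, 112, strain = "B",
                left_flank = 103, right_flank = 113))
  expect_identical(nrow(match_indel_alleles(calls4, pm_cat)), 1L)

  # non-overlapping calls never match, whatever the indices
  calls5 <- bind_calls(manual_call(pm_cat, "I", 100, 101, strain = "A"),
                       manual_call(pm_cat, "I", 103, 104, strain = "B"))
  expect_identical(nrow(match_indel_alleles(calls5, pm_cat)), 2L)

  # kinds never mix
  calls6 <- bind_calls(manual_call(pm_cat, "I", 100, 110, strain = "A"),
                       manual_call(pm_cat, "I", 100, 110, strain = "B",
                                   kind = "amplification"))
  expect_identical(nrow(match_indel_alleles(calls6, pm_cat)), 2L)
})

test_that("matching is transitive and canonical breakpoints are modal", {
  calls <- bind_calls(manual_call(pm_cat, "I", 100, 110, strain = "A"),
                      manual_call(pm_cat, "I", 103, 110, strain = "B"),
                      manual_call(pm_cat, "I", 106, 110, strain = "C"),
                      manual_call(pm_cat, "I", 103, 110, strain = "D"))
  loci <- match_indel_alleles(calls, pm_cat)
  # A-B and B-C match (3 apart); A-C are 6 apart but chained
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$left_index, 103L) # modal left breakpoint
  expect_identical(loci$right_index, 110L)
  expect_true(loci$locus_id[1] %in% attr(loci, "chained"))
})

test_that("the presence/absence matrix is binary over deletion loci in genomic order", {
  calls <- bind_calls(manual_call(pm_cat, "I", 200, 210, strain = "B"),
                      manual_call(pm_cat, "I", 100, 110, strain = "A"),
                      manual_call(pm_cat, "I", 100, 110, strain = "C"),
                      manual_call(pm_cat, "I", 300, 310, strain = "A",
                                  kind = "amplification"))
  loci <- match_indel_alleles(calls, pm_cat)
  mat <- build_presence_absence(loci, c("A", "B", "C"))
  expect_identical(dim(mat), c(3L, 2L))
  expect_identical(unname(mat[, 1]), c(1L, 0L, 1L)) # locus at probe 100 first
  expect_identical(unname(mat[, 2]), c(0L, 1L, 0L))
  # amplifications excluded by default, included on request
  mat2 <- build_presence_absence(loci, c("A", "B", "C"),
                                 kinds = c("deletion", "amplification"))
  expect_identical(ncol(mat2), 3L)
})

test_that("deletions and amplifications over the same probes stay separate loci", {
  calls <- bind_calls(manual_call(pm_cat, "I", 150, 160, strain = "A"),
                      manual_call(pm_cat, "I", 150, 160, strain = "B",
                                  kind = "amplification"))
  loci <- match_indel_alleles(calls, pm_cat)
  mat <- build_presence_absence(loci, c("A", "B"))
  expect_identical(ncol(mat), 1L)
  expect_identical(unname(mat[, 1]), c(1L, 0L)) # only the deletion carrier
})

test_that("gene annotation separates wholly from partially affected genes", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "p1"),
    chrom = "I",
    start = c(2000, 1000, 9000, 3000),
    end = c(3000, 2000, 9500, 3400),
    biotype = c("gene", "gene", "gene", "pseudogene"),
    stringsAsFactors = FALSE
  )
  span <- data.frame(chrom = "I", start = 1500, end = 3500)
  ann <- annotate_genes(span, genes)
  expect_setequal(ann$gene_id, c("g1", "g2", "p1"))
  expect_identical(ann$effect[ann$gene_id == "g1"], "wholly")
  expect_identical(ann$effect[ann$gene_id == "g2"], "partially")
  expect_identical(ann$effect[ann$gene_id == "p1"], "wholly")
})

test_that("gene annotation agrees with a brute-force interval scan", {
  set.seed(3)
  genes <- simulate_gene_annotations(pm_cat, gene_density = 80, seed = 4)
  for (r in 1:20) {
    left <- sample(nrow(pm_cat) - 60, 1)
    span <- data.frame(chrom = "I", start = pm_cat$start[left],
                       end = pm_cat$end[left + sample(5:50, 1)])
    ann <- annotate_genes(span, genes)
    brute <- genes[genes$chrom == span$chrom & genes$start <= span$end &
                     genes$end >= span$start, ]
    expect_setequal(ann$gene_id, brute$gene_id)
    brute_whole <- brute$gene_id[brute$start >= span$start & brute$end <= span$end]
    expect_setequal(ann$gene_id[ann$effect == "wholly"], brute_whole)
  }
})

test_that("region assignment uses the left breakpoint probe midpoint and X overrides", {
  lay <- layout_config(chromosome_names = c("I", "X"),
                       chromosome_lengths = c(2e5, 1e5), arm_fraction = 0.25)
  pm <- generate_probe_map(lay, seed = 21)
  b <- arm_boundaries(pm)
  arm_probe <- which(pm$chrom == "I" & pm$region == "arm")[5]
  cen_probe <- which(pm$chrom == "I" & pm$region == "center")[5]
  x_probe <- which(pm$chrom == "X")[5]
  calls <- bind_calls(
    manual_call(pm, "I", pm$index[arm_probe], pm$index[arm_probe] + 3),
    manual_call(pm, "I", pm$index[cen_probe], pm$index[cen_probe] + 3),
    manual_call(pm, "X", pm$index[x_probe], pm$index[x_probe] + 3))
  expect_identical(assign_region(calls, b, pm), c("arm", "center", "X"))
})

test_that("catalog summaries satisfy their internal accounting identities", {
  set.seed(9)
  strains <- c("A", "B", "C", "D")
  calls <- bind_calls(
    manual_call(pm_cat, "I", 100, 110, strain = "A"),
    manual_call(pm_cat, "I", 100, 110, strain = "B"),
    manual_call(pm_cat, "I", 200, 207, strain = "A"),
    manual_call(pm_cat, "I", 300, 309, strain = "C"),
    manual_call(pm_cat, "I", 400, 404, strain = "A", kind = "amplification"))
  loci <- match_indel_alleles(calls, pm_cat)
  s <- summarize_catalog(calls, loci, strains)
  expect_identical(s$per_strain$deletions, c(2L, 1L, 1L, 0L))
  expect_identical(s$per_strain$amplifications, c(1L, 0L, 0L, 0L))
  ps <- s$pairwise_shared
  expect_true(isSymmetric(ps))
  expect_identical(unname(diag(ps)), c(2L, 1L, 1L, 0L))
  expect_identical(ps["A", "B"], 1L)
  # row diagonal dominates its off-diagonal entries
  expect_true(all(diag(ps) >= apply(ps - diag(diag(ps)), 1, max)))
  # sharing spectrum of each strain sums to its diagonal entry
  for (st in strains) {
    expect_identical(unname(sum(s$sharing_spectrum[[st]])), diag(ps)[[st]])
  }
  expect_identical(unname(s$n_loci["deletion"]), 3L)
})

test_that("two strains sharing every locus fill the pairwise matrix", {
  calls <- bind_calls(manual_call(pm_cat, "I", 100, 110, strain = "A"),
                      manual_call(pm_cat, "I", 100, 110, strain = "B"),
                      manual_call(pm_cat, "I", 300, 310, strain = "A"),
                      manual_call(pm_cat, "I", 300, 310, strain = "B"))
  loci <- match_indel_alleles(calls, pm_cat)
  s <- summarize_catalog(calls, loci, c("A", "B"))
  expect_true(all(s$pairwise_shared == 2L))
})

test_that("chromosome count tests use probe-proportional expectations", {
  # 60 and 40 probes: counts 6 and 4 are exactly probe-proportional
  prof <- rbind(manual_profile(rep(0, 60), chrom = "c1"),
                manual_profile(rep(0, 40), chrom = "c2"))
  pm <- probe_map_for(prof)
  calls <- bind_calls(do.call(rbind, c(
    lapply(1:6, function(i) manual_call(pm, "c1", i * 4, i * 4 + 1)),
    lapply(1:4, function(i) manual_call(pm, "c2", i * 4, i * 4 + 1))
  )))
  st <- run_length_and_count_tests(calls, pm, arm_boundaries(pm),
                                   x_chromosome = "none")
  expect_equal(unname(st$chisq_deletion$statistic), 0, tolerance = 1e-10)
  expect_equal(st$chisq_deletion$p.value, 1)
})

test_that("the chi-square statistic matches the hand computation on equal shares", {
  # 6 chromosomes, equal probe shares, counts (10,10,10,10,10,40):
  # E = 15 each, X^2 = 5*(25/15) + 625/15 = 50, df = 5
  obs <- c(10, 10, 10, 10, 10, 40)
  ct <- suppressWarnings(chisq.test(obs, p = rep(1 / 6, 6)))
  expect_equal(unname(ct$statistic), 50)
  expect_identical(unname(ct$parameter), 5)
})

test_that("length ANOVA drops undersized groups with a warning and the arm test is Welch", {
  set.seed(11)
  calls <- bind_calls(do.call(rbind, c(
    lapply(1:6, function(i) manual_call(pm_cat, "I", i * 30, i * 30 + sample(3:20, 1),
                                        strain = "A")),
    lapply(1:6, function(i) manual_call(pm_cat, "I", 300 + i * 30,
                                        300 + i * 30 + sample(3:20, 1),
                                        strain = "B")),
    list(manual_call(pm_cat, "I", 700, 710, strain = "lonely")))))
  expect_warning(
    st <- run_length_and_count_tests(calls, pm_cat, arm_boundaries(pm_cat)),
    "lonely")
  expect_s3_class(st$anova_strain[[1]], "data.frame")
  expect_equal(st$anova_strain[[1]]$Df[1], 1) # A vs B after dropping
  expect_s3_class(st$ttest_arm_vs_center, "htest")
  expect_match(st$ttest_arm_vs_center$method, "Welch")
})
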