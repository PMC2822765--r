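rand_matrix <- function(n, l, labels = LETTERS[1:n]) {
  repeat {
    m <- matrix(rbinom(n * l, 1, 0.4), n, l,
                dimnames = list(labels, paste0("x", 1:l)))
    if (all(colSums(m) > 0)) return(m)
  }
}

test_that("tree scores match the hand-checkable four-taxon cases", {
  m <- matrix(0L, 4, 1, dimnames = list(c("A", "B", "C", "D"), "l1"))
  m[c("A", "B"), 1] <- 1L
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(wagner_score(t_ab, m), 1)
  expect_identical(wagner_score(t_ac, m), 2)
  expect_identical(camin_sokal_score(t_ac, m), 2) # two origins, no reversal
  m_abc <- m; m_abc[c("A", "B", "C"), 1] <- 1L
  expect_identical(wagner_score(t_ab, m_abc), 1) # one loss at D
  expect_identical(camin_sokal_score(t_ab, m_abc), 2) # reversal forbidden
  # a character in a single taxon costs one origin on every tree
  m1 <- matrix(0L, 4, 1, dimnames = list(c("A", "B", "C", "D"), "x"))
  m1["C", 1] <- 1L
  expect_identical(camin_sokal_score(t_ab, m1), 1)
  expect_identical(camin_sokal_score(t_ac, m1), 1)
  # no variation, no changes
  expect_identical(wagner_score(t_ab, matrix(0L, 4, 3,
                                             dimnames = list(c("A", "B", "C", "D"), NULL))), 0)
})

test_that("scores agree with brute-force enumeration over internal states", {
  set.seed(61)
  for (n in c(4, 5, 6)) {
    labels <- LETTERS[1:n]
    for (r in 1:8) {
      m <- rand_matrix(n, 5, labels)
      tr <- ape::rtree(n, tip.label = sample(labels), br = NULL)
      expect_identical(wagner_score(tr, m), brute_score(tr, m, "wagner"))
      expect_identical(camin_sokal_score(tr, m), brute_score(tr, m, "camin_sokal"))
      # irreversibility can never reduce the number of changes
      expect_gte(camin_sokal_score(tr, m), wagner_score(tr, m))
    }
  }
})

test_that("branch-and-bound equals exhaustive search at n = 6", {
  set.seed(67)
  for (r in 1:10) {
    m <- rand_matrix(6, 8)
    for (method in c("wagner", "camin_sokal")) {
      ex <- search_most_parsimonious(m, method, "exhaustive")
      bb <- search_most_parsimonious(m, method, "branch_and_bound")
      expect_identical(bb$score, ex$score)
      key <- function(trs) sort(vapply(trs, function(tr) {
        paste(cghindels:::split_keys(tr)$all, collapse = ";")
      }, character(1)))
      expect_identical(key(bb$trees), key(ex$trees))
    }
  }
})

test_that("the exhaustive optimum is the true minimum over all topologies", {
  set.seed(71)
  m <- rand_matrix(6, 6)
  topo <- all_topologies(rownames(m))
  for (method in c("wagner", "camin_sokal")) {
    scorer <- if (method == "wagner") wagner_score else camin_sokal_score
    best <- min(vapply(topo, scorer, numeric(1), pa_matrix = m))
    if (method == "camin_sokal") {
      # rooted-search optimum can only be at most the best trifurcation-rooted
      # score, and never below the Wagner optimum
      ex <- search_most_parsimonious(m, method, "exhaustive")
      expect_lte(ex$score, best)
      expect_gte(ex$score,
                 search_most_parsimonious(m, "wagner", "exhaustive")$score)
    } else {
      expect_identical(search_most_parsimonious(m, method, "exhaustive")$score,
                       best)
    }
  }
})

test_that("compatible characters marking every branch identify the tree uniquely", {
  strains <- LETTERS[1:6]
  groups <- c(list(c("A", "B"), c("C", "D"), c("E", "F")),
              as.list(strains))
  m <- matrix(0L, 6, length(groups) * 3,
              dimnames = list(strains, paste0("c", 1:(length(groups) * 3))))
  for (i in seq_along(groups)) {
    for (k in 0:2) m[groups[[i]], i + k * length(groups)] <- 1L
  }
  truth <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  for (method in c("wagner", "camin_sokal")) {
    res <- search_most_parsimonious(m, method, "exhaustive")
    expect_identical(length(res$trees), 1L)
    expect_identical(ape::dist.topo(ape::unroot(res$trees[[1]]),
                                    ape::unroot(truth))[1], 0)
    h <- search_most_parsimonious(m, method, "heuristic", seed = 3)
    expect_identical(h$score, res$score)
  }
})

test_that("a single informative character ties every tree containing its bipartition", {
  m <- matrix(0L, 6, 2, dimnames = list(LETTERS[1:6], c("c1", "c2")))
  m[c("A", "B"), 1] <- 1L
  m["C", 2] <- 1L # uninformative filler so l >= 2
  res <- search_most_parsimonious(m, "wagner", "exhaustive")
  expect_identical(res$score, 2)
  # trees with the A|B cherry: 15 of the 105 six-taxon topologies
  expect_identical(length(res$trees), 15L)
  ab <- canon_key(c("A", "B"), LETTERS[1:6])
  for (tr in res$trees) {
    expect_true(ab %in% cghindels:::split_keys(tr)$all)
  }
})

test_that("bootstrap consensus recovers a clonal genealogy with high support", {
  strains <- LETTERS[1:6]
  groups <- c(list(c("A", "B"), c("C", "D"), c("E", "F")), as.list(strains))
  m <- matrix(0L, 6, length(groups) * 6,
              dimnames = list(strains, paste0("c", 1:(length(groups) * 6))))
  for (i in seq_along(groups)) {
    for (k in 0:5) m[groups[[i]], i + k * length(groups)] <- 1L
  }
  truth <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  for (method in c("wagner", "camin_sokal")) {
    cons <- bootstrap_consensus(m, method, n_replicates = 60, seed = 5)
    expect_identical(ape::dist.topo(ape::unroot(cons$tree),
                                    ape::unroot(truth))[1], 0)
    maj <- cons$support[cons$support$pct > 50, ]
    expect_true(all(maj$pct >= 95))
    # supports live in (50, 100] and consensus splits are compatible by
    # construction (the tree was built from them)
    expect_true(all(maj$pct <= 100))
  }
})

test_that("a constant bootstrap column set yields 100% support everywhere", {
  strains <- LETTERS[1:6]
  m <- matrix(0L, 6, 4, dimnames = list(strains, paste0("c", 1:4)))
  m[c("A", "B"), ] <- 1L # every column identical
  cons <- bootstrap_consensus(m, "wagner", n_replicates = 20, seed = 9)
  expect_true(canon_key(c("A", "B"), strains) %in%
                cons$support$split[cons$support$pct > 100 - 1e-6])
})

test_that("bootstrap results are reproducible bit-for-bit given the seed", {
  set.seed(91)
  m <- rand_matrix(6, 20)
  c1 <- bootstrap_consensus(m, "camin_sokal", n_replicates = 25, seed = 13)
  c2 <- bootstrap_consensus(m, "camin_sokal", n_replicates = 25, seed = 13)
  expect_identical(c1$support, c2$support)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
  c3 <- bootstrap_consensus(m, "camin_sokal", n_replicates = 25, seed = 14)
  expect_false(identical(c1$support, c3$support))
})

test_that("group frequencies count tied trees fractionally and match supports", {
  strains <- LETTERS[1:6]
  groups <- c(list(c("A", "B"), c("C", "D"), c("E", "F")), as.list(strains))
  m <- matrix(0L, 6, length(groups) * 4,
              dimnames = list(strains, paste0("c", 1:(length(groups) * 4))))
  for (i in seq_along(groups)) {
    for (k in 0:3) m[groups[[i]], i + k * length(groups)] <- 1L
  }
  cons <- bootstrap_consensus(m, "wagner", n_replicates = 30, seed = 17)
  ab <- group_frequency(cons, c("A", "B"))
  expect_equal(ab, cons$support$pct[cons$support$split ==
                                      canon_key(c("A", "B"), strains)],
               tolerance = 1e-9)
  # complements name the same bipartition
  expect_equal(group_frequency(cons, c("C", "D", "E", "F")), ab)
})

test_that("mismatched strains and undersized problems are rejected", {
  m <- rand_matrix(4, 3)
  tr <- ape::read.tree(text = "((A,B),(X,Y));")
  expect_error(wagner_score(tr, m), "differ")
  expect_error(search_most_parsimonious(rand_matrix(3, 3), "wagner"),
               "at least 4")
  expect_error(search_most_parsimonious(rand_matrix(9, 3), "wagner",
                                        "exhaustive"), "branch_and_bound")
})
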