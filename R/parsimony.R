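# Strain trees from deletion presence/absence markers.
#
# Wagner parsimony treats gain and loss of a deletion as equally likely
# with no assumed ancestral state; Camin-Sokal parsimony treats deletions
# as derived and forbids reversal, scoring trees rooted at a hypothetical
# ancestor that carries no deletions.

ANC_LABEL <- ".ANC"

# convert a phylo to the 0-based edge matrix + state matrix the C++
# scorer expects (tips 0..n-1 in tree$tip.label order, internals >= n)
phylo_states <- function(tree, pa_matrix) {
  if (!setequal(tree$tip.label, rownames(pa_matrix))) {
    stopf("tree tip labels and matrix strains differ")
  }
  states <- pa_matrix[tree$tip.label, , drop = FALSE]
  storage.mode(states) <- "integer"
  list(edge = tree$edge - 1L, states = states)
}

#' Wagner parsimony score of a tree
#'
#' Sum over loci of the minimum number of character state changes (gains
#' and losses weighted equally) needed to explain the presence/absence
#' pattern on the tree; root placement is immaterial.
#'
#' @param tree An `ape::phylo` whose tips are the matrix's strains.
#' @param pa_matrix Binary presence/absence matrix (strains x loci).
#' @return Integer-valued score.
#' @export
wagner_score <- function(tree, pa_matrix) {
  ps <- phylo_states(tree, pa_matrix)
  score_tree_cpp(ps$edge, ps$states, rep(1, ncol(ps$states)), 0L, -1L)
}

#' Camin-Sokal parsimony score of a tree
#'
#' Deletions are derived states: transitions from absence to presence are
#' allowed but reversals are forbidden.  A hypothetical all-absent
#' ancestor is attached at the tree's root node, and each locus costs one
#' gain per maximal subtree whose strains all carry the deletion.
#'
#' @inheritParams wagner_score
#' @return Integer-valued score (always >= the Wagner score).
#' @export
camin_sokal_score <- function(tree, pa_matrix) {
  ps <- phylo_states(tree, pa_matrix)
  n <- nrow(ps$states)
  # make room for the ancestor leaf at id n: shift internal ids up by one
  edge <- ps$edge
  edge[edge >= n] <- edge[edge >= n] + 1L
  root <- n + 1L # the phylo root node (was id n)
  edge <- rbind(edge, c(root, n))
  states <- rbind(ps$states, rep(0L, ncol(ps$states)))
  score_tree_cpp(edge, states, rep(1, ncol(states)), 1L, n)
}

# collapse duplicate locus columns into pattern weights
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = "")
  first <- !duplicated(key)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]))
}

# canonical split keys (side not containing `labels[1]`, sorted, joined
# with "|") for every internal edge of a 0-based C++ edge matrix
edge_matrix_splits <- function(em, labels) {
  n_all <- length(labels)
  maxid <- max(em) + 1L
  adj <- vector("list", maxid)
  for (r in seq_len(nrow(em))) {
    a <- em[r, 1] + 1L; b <- em[r, 2] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  strains <- setdiff(labels, ANC_LABEL)
  keys <- character(0)
  for (r in seq_len(nrow(em))) {
    # tips on the side of em[r, 2]
    seen <- logical(maxid)
    seen[em[r, 1] + 1L] <- TRUE
    stack <- em[r, 2] + 1L
    seen[stack] <- TRUE
    side <- character(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n_all) side <- c(side, labels[v])
      for (u in adj[[v]]) {
        if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
      }
    }
    side <- setdiff(side, ANC_LABEL)
    if (strains[1] %in% side) side <- setdiff(strains, side)
    if (length(side) >= 2 && length(side) <= length(strains) - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(keys))
}

# build an unrooted phylo from a laminar family of splits (each a subset
# of `labels` not containing labels[1]); optional labels for each split
tree_from_splits <- function(splits, labels, support = NULL) {
  sizes <- vapply(splits, length, integer(1))
  ord <- order(sizes, decreasing = TRUE)
  splits <- splits[ord]
  support <- if (is.null(support)) rep("", length(splits)) else as.character(support[ord])
  k <- length(splits)
  parent <- integer(k) # 0 = top
  if (k > 1) {
    for (i in 2:k) {
      for (j in (i - 1):1) {
        if (all(splits[[i]] %in% splits[[j]])) { parent[i] <- j; break }
      }
    }
  }
  leaf_parent <- vapply(labels, function(lab) {
    best <- 0L
    best_size <- Inf
    for (j in seq_len(k)) {
      if (lab %in% splits[[j]] && length(splits[[j]]) < best_size) {
        best <- j; best_size <- length(splits[[j]])
      }
    }
    best
  }, integer(1))
  quote_label <- function(lab) {
    if (grepl("[[:space:](),:;]", lab)) paste0("'", lab, "'") else lab
  }
  # recursive newick construction
  nwk <- function(node) {
    kids_cl <- which(parent == node)
    kids_lf <- names(leaf_parent)[leaf_parent == node]
    parts <- c(vapply(kids_lf, quote_label, character(1)),
               vapply(kids_cl, nwk, character(1)))
    lab <- if (node == 0) "" else support[node]
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  text <- paste0(nwk(0L), ";")
  ape::read.tree(text = text)
}

# convert one C++ search result tree to an unrooted phylo over strains
cpp_tree_to_phylo <- function(em, labels) {
  strains <- setdiff(labels, ANC_LABEL)
  keys <- edge_matrix_splits(em, labels)
  splits <- lapply(keys, function(key) strsplit(key, "|", fixed = TRUE)[[1]])
  tree_from_splits(splits, strains)
}

#' Search for most parsimonious trees
#'
#' Finds the optimal unrooted strain trees under Wagner or Camin-Sokal
#' parsimony.  `exhaustive` enumerates every unrooted topology (feasible
#' up to 8 strains), `branch_and_bound` is exact with pruning (the score
#' of a partial tree can only grow as taxa are added), and `heuristic`
#' performs seeded stepwise addition with jumbled input orders followed by
#' nearest-neighbour-interchange refinement.  Under Camin-Sokal the
#' hypothetical all-absent ancestor participates in the search as the
#' root, and is removed from the reported trees.
#'
#' @param pa_matrix Binary presence/absence matrix (strains x loci).
#' @param method `"wagner"` or `"camin_sokal"`.
#' @param strategy `"exhaustive"`, `"branch_and_bound"` or `"heuristic"`.
#' @param n_jumble Jumbled addition orders for the heuristic.
#' @param seed Seed for the heuristic's jumbling.
#' @return List: `trees` (all tied-optimal `phylo` objects found) and
#'   `score`.
#' @export
search_most_parsimonious <- function(pa_matrix,
                                     method = c("wagner", "camin_sokal"),
                                     strategy = c("branch_and_bound",
                                                  "exhaustive", "heuristic"),
                                     n_jumble = 10L, seed = 1L) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  n <- nrow(pa_matrix)
  if (n < 4) stopf("need at least 4 strains")
  if (strategy == "exhaustive" && n > 8) {
    stopf("exhaustive enumeration is limited to 8 strains; use branch_and_bound (exact) or heuristic")
  }
  if (is.null(rownames(pa_matrix))) {
    rownames(pa_matrix) <- paste0("strain", seq_len(n))
  }
  states <- pa_matrix
  storage.mode(states) <- "integer"
  if (method == "camin_sokal") {
    states <- rbind(matrix(0L, 1, ncol(states), dimnames = list(ANC_LABEL)),
                    states)
  }
  labels <- rownames(states)
  cp <- compress_patterns(states)
  strat_code <- c(exhaustive = 0L, branch_and_bound = 1L, heuristic = 2L)[[strategy]]
  res <- pars_search_cpp(cp$states, cp$weights,
                         if (method == "camin_sokal") 1L else 0L,
                         strat_code, as.integer(n_jumble), as.integer(seed))
  trees <- lapply(res$trees, cpp_tree_to_phylo, labels = labels)
  # distinct strain topologies (for Camin-Sokal, distinct rooted trees can
  # collapse to one unrooted tree once the ancestor is removed)
  keys <- vapply(trees, function(tr) {
    paste(sort(split_keys(tr)$all), collapse = ";")
  }, character(1))
  list(trees = trees[!duplicated(keys)], score = res$score)
}

# canonical split keys of a phylo (over its own tip set)
split_keys <- function(tree) {
  strains <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (strains[1] %in% side) side <- setdiff(strains, side)
    if (length(side) >= 2 && length(side) <= length(strains) - 2) {
      paste(sort(side), collapse = "|")
    } else {
      NA_character_
    }
  }, character(1))
  keys <- sort(unique(keys[!is.na(keys)]))
  # trivial splits (cherries etc. already covered); also collect every
  # internal edge by rooting at tip 1 is handled by prop.part
  list(all = keys)
}

#' Bootstrap consensus tree with per-bipartition support
#'
#' Draws `n_replicates` bootstrap samples of loci (columns) with
#' replacement, infers the optimal tree(s) for each replicate under the
#' requested parsimony method, and counts bipartitions across replicates
#' (tied-optimal trees contribute fractionally, 1/k each).  Returns the
#' majority-rule (> 50%) consensus with support percentages, plus the
#' archive of replicate bipartitions for group-frequency queries.
#'
#' @inheritParams search_most_parsimonious
#' @param n_replicates Bootstrap replicates.
#' @param strategy Search strategy per replicate (heuristic by default).
#' @param seed Root seed; replicate resampling and search jumbling derive
#'   from it deterministically.
#' @return List of class `bootstrap_consensus`: `tree` (consensus `phylo`
#'   with support percentages as node labels), `support` (data frame of
#'   split key and percentage), `archive` (per replicate, the list of
#'   tied-optimal trees' split-key vectors), `method`, `n_replicates`.
#' @export
bootstrap_consensus <- function(pa_matrix,
                                method = c("wagner", "camin_sokal"),
                                n_replicates = 1000L, seed = 1L,
                                strategy = "heuristic", n_jumble = 10L) {
  method <- match.arg(method)
  l <- ncol(pa_matrix)
  if (l < 2) stopf("need at least 2 loci")
  strains <- rownames(pa_matrix)
  seeds <- derive_child_seeds(seed, 2L * n_replicates)
  counts <- new.env(parent = emptyenv())
  archive <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- with_seed(seeds[r], sample.int(l, l, replace = TRUE))
    rep_mat <- pa_matrix[, cols, drop = FALSE]
    res <- search_most_parsimonious(rep_mat, method = method,
                                    strategy = strategy, n_jumble = n_jumble,
                                    seed = seeds[n_replicates + r])
    ktrees <- lapply(res$trees, function(tr) split_keys(tr)$all)
    archive[[r]] <- ktrees
    wt <- 1 / length(ktrees)
    for (keys in ktrees) {
      for (key in keys) {
        counts[[key]] <- (counts[[key]] %||% 0) + wt
      }
    }
  }
  keys <- ls(counts)
  pct <- vapply(keys, function(k) 100 * counts[[k]] / n_replicates, numeric(1))
  keep <- pct > 50
  support <- data.frame(split = keys, pct = pct, stringsAsFactors = FALSE,
                        row.names = NULL)
  support <- support[order(-support$pct), , drop = FALSE]
  maj <- which(keep)
  tree <- tree_from_splits(
    lapply(keys[maj], function(k) strsplit(k, "|", fixed = TRUE)[[1]]),
    strains,
    sprintf("%g", round(pct[maj], 1))
  )
  structure(list(tree = tree, support = support, archive = archive,
                 method = method, n_replicates = n_replicates),
            class = "bootstrap_consensus")
}

#' Bootstrap frequency of a strain group
#'
#' Fraction of bootstrap replicates whose optimal tree(s) contain the
#' bipartition separating `group` from the remaining strains, with
#' tied-optimal trees counted fractionally.
#'
#' @param consensus A [bootstrap_consensus()] result.
#' @param group Character vector of strain labels.
#' @param strains All strain labels (defaults to the consensus tree's
#'   tips).
#' @return Percentage in `[0, 100]`.
#' @export
group_frequency <- function(consensus, group, strains = NULL) {
  strains <- sort(strains %||% consensus$tree$tip.label)
  side <- sort(group)
  if (strains[1] %in% side) side <- setdiff(strains, side)
  key <- paste(sort(side), collapse = "|")
  hits <- vapply(consensus$archive, function(ktrees) {
    mean(vapply(ktrees, function(keys) key %in% keys, logical(1)))
  }, numeric(1))
  100 * mean(hits)
}
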