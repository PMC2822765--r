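# Independent oracles used to freeze expected values.  These are written
# for clarity, not speed, and stay independent of the implementation paths
# they check.

# exhaustive least-squares 3-segment change-point search: returns the
# (first, last) probe of the middle segment minimizing total RSS
ls_changepoint3 <- function(x) {
  n <- length(x)
  rss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- NULL
  best_rss <- Inf
  for (i in 1:n) {
    for (j in i:n) {
      r <- rss(if (i > 1) x[1:(i - 1)] else numeric(0)) +
        rss(x[i:j]) +
        rss(if (j < n) x[(j + 1):n] else numeric(0))
      if (r < best_rss - 1e-12) {
        best_rss <- r
        best <- c(i, j)
      }
    }
  }
  best
}

# eager reference for the bottom-up merger: recompute the Welch P of every
# adjacent pair at each step, merge the leftmost maximum while it is >= alpha
eager_segment <- function(x, alpha, gsd) {
  segs <- lapply(seq_along(x), function(i) c(i, i))
  welch <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    m1 <- mean(a); m2 <- mean(b)
    use_z <- n1 < 2 || n2 < 2
    va <- if (n1 < 2) gsd^2 else var(a)
    vb <- if (n2 < 2) gsd^2 else var(b)
    se2 <- va / n1 + vb / n2
    if (se2 <= 0) return(if (m1 == m2) 1 else 0)
    t <- (m1 - m2) / sqrt(se2)
    if (use_z) return(2 * pnorm(-abs(t)))
    den <- (va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1)
    df <- if (den <= 0) n1 + n2 - 2 else se2^2 / den
    2 * pt(-abs(t), df)
  }
  repeat {
    if (length(segs) < 2) break
    ps <- vapply(seq_len(length(segs) - 1), function(k) {
      welch(x[segs[[k]][1]:segs[[k]][2]], x[segs[[k + 1]][1]:segs[[k + 1]][2]])
    }, numeric(1))
    k <- which.max(ps)
    if (ps[k] < alpha) break
    segs[[k]] <- c(segs[[k]][1], segs[[k + 1]][2])
    segs[[k + 1]] <- NULL
  }
  do.call(rbind, segs)
}

# brute-force small parsimony for one binary character: enumerate every
# assignment of states to the internal nodes of a rooted phylo
brute_wagner_char <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- tip_states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    node_state <- as.integer(intToBits(mask)[1:nnode])
    full <- c(states, node_state)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute force under irreversibility: the root (a hypothetical all-absent
# ancestor attached at the phylo's root node) has state 0 and 1 -> 0
# transitions are forbidden
brute_cs_char <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- tip_states[tree$tip.label]
  root <- ntip + 1
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    node_state <- as.integer(intToBits(mask)[1:nnode])
    full <- c(states, node_state)
    losses <- sum(full[tree$edge[, 1]] == 1 & full[tree$edge[, 2]] == 0)
    if (losses > 0) next
    # the all-absent ancestor hangs off the root: a root in state 1 is
    # itself one gain
    gains <- full[root] +
      sum(full[tree$edge[, 1]] == 0 & full[tree$edge[, 2]] == 1)
    best <- min(best, gains)
  }
  best
}

brute_score <- function(tree, pa_matrix, method) {
  f <- if (method == "wagner") brute_wagner_char else brute_cs_char
  sum(vapply(seq_len(ncol(pa_matrix)), function(j) {
    f(tree, pa_matrix[, j])
  }, numeric(1)))
}

# all unrooted topologies over the given labels (phangorn's enumerator,
# independent of the package's own stepwise enumeration)
all_topologies <- function(labels) {
  tt <- phangorn::allTrees(length(labels), rooted = FALSE,
                           tip.label = labels)
  lapply(seq_along(tt), function(i) tt[[i]]) # [[ restores shared tip labels
}

# canonical split key for a strain group: the side not containing the
# alphabetically first strain, sorted and joined with "|"
canon_key <- function(group, strains) {
  strains <- sort(strains)
  side <- sort(group)
  if (strains[1] %in% side) side <- setdiff(strains, side)
  paste(sort(side), collapse = "|")
}

# independent Haubold-Hudson computation of the standardized index of
# association, written directly from the defining formulas
brute_ias <- function(mat) {
  n <- nrow(mat)
  l <- ncol(mat)
  d <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sum(mat[i, ] != mat[j, ]))
    }
  }
  V_D <- sum((d - mean(d))^2) / length(d)
  V_e <- 0
  for (k in 1:l) {
    p <- mean(mat[, k])
    V_e <- V_e + (n / (n - 1)) * (1 - p^2 - (1 - p)^2)
  }
  (V_D / V_e - 1) / (l - 1)
}
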