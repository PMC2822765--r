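#' Standardized index of association
#'
#' Multilocus linkage disequilibrium statistic of Haubold & Hudson.  For
#' each of the n(n-1)/2 strain pairs the mismatch distance d is the number
#' of loci at which the pair differs.  `V_D` is the (population) variance
#' of the d values and `V_e = sum_j h_j` its expectation at linkage
#' equilibrium, where `h_j = (n/(n-1)) (1 - sum_alleles p^2)` is the
#' unbiased per-locus diversity.  Then
#' `I_A^S = (V_D / V_e - 1) / (l - 1)`, which is 0 in expectation at
#' linkage equilibrium and grows with inter-locus association.
#'
#' @param pa_matrix Binary presence/absence matrix (strains x loci), no
#'   constant columns.
#' @return List of class `ld_result`: `ia_s`, `V_D`, `V_e`, `l`, `n`
#'   (and `p_value`, `n_permutations` after
#'   [ia_s_permutation_test()]).
#' @export
ia_s <- function(pa_matrix) {
  n <- nrow(pa_matrix)
  l <- ncol(pa_matrix)
  if (n < 3) stopf("need at least 3 strains")
  if (l < 2) stopf("need at least 2 loci")
  freq <- colMeans(pa_matrix)
  if (any(freq == 0 | freq == 1)) {
    stopf("constant columns are not allowed (zero diversity contributes ambiguously to V_e); drop them first")
  }
  d <- as.numeric(dist(pa_matrix, method = "manhattan"))
  V_D <- mean(d^2) - mean(d)^2
  h <- (n / (n - 1)) * (1 - freq^2 - (1 - freq)^2)
  V_e <- sum(h)
  structure(list(
    ia_s = (V_D / V_e - 1) / (l - 1),
    V_D = V_D, V_e = V_e, l = l, n = n,
    p_value = NA_real_, n_permutations = 0L
  ), class = "ld_result")
}

#' Monte Carlo significance test for the index of association
#'
#' Generates the linkage-equilibrium null by independently permuting each
#' locus's alleles among the strains (destroying inter-locus association
#' while preserving every allele frequency) and recomputing `I_A^S`.  The
#' P value is the proportion of null statistics at least as large as the
#' observed one, with the +1 correction so P is never exactly 0.
#'
#' @inheritParams ia_s
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return An `ld_result` with `p_value` and `n_permutations` filled in,
#'   plus the vector of `null` statistics.
#' @export
ia_s_permutation_test <- function(pa_matrix, n_permutations = 1000L, seed = 1L) {
  obs <- ia_s(pa_matrix)
  n <- nrow(pa_matrix)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- apply(pa_matrix, 2, function(col) col[sample.int(n)])
      rownames(perm) <- rownames(pa_matrix)
      ia_s(perm)$ia_s
    }, numeric(1))
  })
  obs$p_value <- (1 + sum(null >= obs$ia_s)) / (n_permutations + 1)
  obs$n_permutations <- as.integer(n_permutations)
  obs$null <- null
  obs
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("I_A^S = %.4f (n = %d strains, l = %d loci)\n", x$ia_s, x$n, x$l))
  if (!is.na(x$p_value)) {
    cat(sprintf("Monte Carlo P = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}
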