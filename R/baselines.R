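#' Pairwise likelihood ratio of co-mutation
#'
#' `f12 / (f1 * f2)` with per-sample empirical frequencies: the observed
#' co-mutation frequency relative to independence. Values below 1 signal
#' exclusivity; genes never mutated in the same sample give exactly 0 no
#' matter how few mutations each carries — the statistic's known
#' low-coverage false-positive mode.
#'
#' @param x mutation matrix.
#' @param pair two gene labels, each mutated in at least one sample.
#' @return non-negative real.
#' @export
likelihood_ratio <- function(x, pair) {
  x <- as_mutation_matrix(x)
  pair <- check_genes(x, pair)
  if (length(pair) != 2) stop("pair must contain exactly 2 distinct genes")
  f <- colMeans(x[, pair, drop = FALSE])
  if (any(f == 0)) stop("likelihood ratio undefined: gene with no mutations")
  f12 <- mean(x[, pair[1]] & x[, pair[2]])
  unname(f12 / (f[1] * f[2]))
}

#' Hypergeometric exclusivity p-value of a gene pair
#'
#' With k samples and marginal mutation counts n1, n2, the probability of
#' observing at most the actual overlap when a fixed n1-set and n2-set are
#' placed uniformly at random among the k samples: small values mean the
#' genes overlap less than chance expects.
#'
#' @inheritParams likelihood_ratio
#' @return probability in (0, 1\].
#' @export
hypergeom_exclusivity_p <- function(x, pair) {
  x <- as_mutation_matrix(x)
  pair <- check_genes(x, pair)
  if (length(pair) != 2) stop("pair must contain exactly 2 distinct genes")
  n1 <- sum(x[, pair[1]]); n2 <- sum(x[, pair[2]])
  if (n1 == 0 || n2 == 0) stop("hypergeometric p undefined: gene with no mutations")
  ov <- sum(x[, pair[1]] & x[, pair[2]])
  stats::phyper(ov, n1, nrow(x) - n1, n2)
}

pair_stat_matrix <- function(x, method) {
  k <- nrow(x)
  n <- colSums(x)
  ov <- crossprod(x)
  if (method == "likelihood_ratio") {
    f <- n / k
    s <- (ov / k) / outer(f, f)
  } else {
    n1 <- matrix(n, ncol(x), ncol(x))
    s <- matrix(stats::phyper(ov, n1, k - n1, t(n1)), ncol(x), ncol(x),
                dimnames = dimnames(ov))
  }
  s
}

#' All-pairs exclusivity statistics
#'
#' @param x mutation matrix (every gene mutated at least once).
#' @param method `"likelihood_ratio"` or `"hypergeometric"`; for both,
#'   smaller values are more exclusive.
#' @return data frame with `gene_a`, `gene_b`, `statistic` for all unordered
#'   pairs.
#' @export
pair_statistics <- function(x, method = c("likelihood_ratio", "hypergeometric")) {
  method <- match.arg(method)
  x <- as_mutation_matrix(x)
  if (ncol(x) < 2) stop("need at least 2 genes")
  if (any(colSums(x) == 0))
    stop("genes with no mutations: ",
         paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  s <- pair_stat_matrix(x, method)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  data.frame(gene_a = colnames(x)[idx[, 1]], gene_b = colnames(x)[idx[, 2]],
             statistic = s[idx], stringsAsFactors = FALSE)
}

#' Permutation-corrected pairwise exclusivity significance
#'
#' Null matrices are generated by permuting each gene's column independently,
#' preserving per-gene mutation frequencies while breaking dependence between
#' genes. Two correction schemes:
#' * `"per_pair"` (default): a pair's corrected significance is the fraction
#'   of permutations in which the same pair's permuted statistic is at least
#'   as extreme (small) as observed.
#' * `"max"`: family-wise — the fraction of permutations whose most extreme
#'   statistic over all pairs is at least as extreme as the pair's observed
#'   statistic. Note the likelihood ratio saturates at 0, so under this
#'   scheme any chance-disjoint pair in a permutation masks all real pairs.
#'
#' Deterministic given `seed`.
#'
#' @inheritParams pair_statistics
#' @param n_permutations number of permuted null matrices (>= 1).
#' @param seed integer RNG seed.
#' @param scheme correction scheme, see above.
#' @return data frame with `gene_a`, `gene_b`, `statistic`,
#'   `corrected_significance`, `n_permutations`.
#' @export
permutation_correction <- function(x,
                                   method = c("likelihood_ratio", "hypergeometric"),
                                   n_permutations = 1000, seed = 1,
                                   scheme = c("per_pair", "max")) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  x <- as_mutation_matrix(x)
  obs <- pair_statistics(x, method)
  k <- nrow(x)
  up <- upper.tri(matrix(0, ncol(x), ncol(x)))
  hits <- numeric(nrow(obs))
  best <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      xp <- apply(x, 2L, function(col) col[sample.int(k)])
      dimnames(xp) <- dimnames(x)
      sp <- pair_stat_matrix(xp, method)[up]
      if (scheme == "per_pair") hits <- hits + (sp <= obs$statistic)
      else best[b] <- min(sp)
    }
  })
  obs$corrected_significance <- if (scheme == "per_pair") hits / n_permutations
  else vapply(obs$statistic, function(s) mean(best <= s), numeric(1))
  obs$n_permutations <- as.integer(n_permutations)
  obs
}
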