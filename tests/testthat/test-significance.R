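test_that("log_star follows the universal integer code", {
  c0 <- 2.865064
  expect_equal(log_star(1, c0), log2(c0))
  expect_equal(log_star(2, c0), log2(c0) + 1, tolerance = 1e-12)
  expect_equal(log_star(2, c0), 2.5186, tolerance = 1e-4)
  # hand-iterated value: log2(c) + log2(20) + log2(log2(20)) + ... while > 0
  t1 <- log2(20); t2 <- log2(t1); t3 <- log2(t2); t4 <- log2(t3)
  stopifnot(t4 > 0, log2(t4) < 0)
  expect_equal(log_star(20, c0), log2(c0) + t1 + t2 + t3 + t4,
               tolerance = 1e-12)
  xs <- 1:10000
  expect_true(all(diff(log_star(xs, c0)) >= 0))
  expect_error(log_star(0.5), "x >= 1")
})

test_that("background frequency is the overall aberration rate", {
  x <- bin_matrix(c("10", "01"))
  expect_equal(background_frequency(x), 0.5)
  # Fig-1d-style arithmetic: 13.38 aberrant genes per sample over 1290 genes
  expect_equal(13.38 / 1290, 0.010372, tolerance = 1e-4)
  set.seed(3)
  m <- as_mutation_matrix(matrix(rbinom(80, 1, 0.3), 8, 10,
                                 dimnames = list(paste0("s", 1:8),
                                                 paste0("g", 1:10))))
  p <- background_frequency(m)
  mp <- as_mutation_matrix(m[sample(8), sample(10)])
  expect_equal(background_frequency(mp), p)
  expect_error(background_frequency(bin_matrix(c("00", "00"))), "degenerate")
  expect_error(background_frequency(bin_matrix(c("11", "11"))), "degenerate")
})

test_that("submatrix sorting is canonical and charges ties as configured", {
  x <- bin_matrix(c("01", "11", "10", "00"))
  s <- sort_submatrix(x)
  # tied count-1 rows are ordered by pattern under the canonical column
  # order, so "10" precedes "01"
  expect_equal(rowSums(s$submatrix), c(s2 = 2, s3 = 1, s1 = 1, s4 = 0))
  expect_true(all(diff(colSums(s$submatrix)) <= 0))
  expect_equal(s$sort_bits, 0)
  # rows with counts (2,2,1): one group of two ties -> log2(2!) = 1 bit;
  # column counts (3,2) are distinct and add nothing
  x2 <- bin_matrix(c("11", "11", "10"))
  expect_equal(sort_submatrix(x2, "tie_groups")$sort_bits, 1)
  expect_equal(sort_submatrix(x2, "full_permutation")$sort_bits,
               (lfactorial(3) + lfactorial(2)) / log(2))
  # permuting input rows changes neither sorted output nor bits
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rbinom(35, 1, 0.4), 7, 5,
                dimnames = list(paste0("s", 1:7), paste0("g", 1:5)))
    sa <- sort_submatrix(m, "tie_groups")
    sb <- sort_submatrix(m[sample(7), ], "tie_groups")
    expect_equal(unname(sa$submatrix), unname(sb$submatrix))
    expect_equal(sa$sort_bits, sb$sort_bits)
  }
})

test_that("per-cell probabilities follow the exclusivity posterior", {
  # row already has a one: epsilon no matter the counts
  expect_equal(rme_cell_probability(5, 3, TRUE, 10, 0.01), 0.01)
  # gene exhausted: epsilon
  expect_equal(rme_cell_probability(0, 3, FALSE, 10, 0.01), 0.01)
  # sample exhausted: epsilon
  expect_equal(rme_cell_probability(2, 0, FALSE, 10, 0.01), 0.01)
  # 1-row, 2-column state with gene counts (1,1): first cell gets 1/2
  expect_equal(rme_cell_probability(1, 1, FALSE, 2, 0.01), 0.5)
  # clamped into (0,1)
  expect_equal(rme_cell_probability(3, 1, FALSE, 3, 0.01), 0.99)
})

test_that("encoding gain matches the step-trace reference on random inputs", {
  expect_equal(encoding_gain(matrix(integer(0), 0, 0), 0.1), 0)
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:12, 1); m <- sample(2:5, 1)
    sub <- matrix(rbinom(k * m, 1, runif(1, 0.1, 0.6)), k, m,
                  dimnames = list(paste0("s", 1:k), paste0("g", 1:m)))
    p0 <- runif(1, 0.01, 0.3)
    eps <- runif(1, 0.001, 0.05)
    expect_equal(encoding_gain(sub, p0, significance_config(epsilon = eps)),
                 ref_encoding_gain(sub, p0, eps), tolerance = 1e-10)
  }
})

test_that("a perfectly exclusive full-coverage module compresses", {
  sub <- equal_module_matrix(k = 100, m = 3, coverage = 1, exclusivity = 1)
  expect_gt(encoding_gain(sort_submatrix(sub)$submatrix, 13.38 / 1290), 0)
})

test_that("d_score assembles the penalties and caps significance at 1", {
  set.seed(21)
  x <- as_mutation_matrix(matrix(rbinom(300, 1, 0.15), 30, 10,
                                 dimnames = list(paste0("s", 1:30),
                                                 paste0("g", 1:10))))
  br <- d_score(x, c("g1", "g2", "g3"), n_total = 500)
  expect_s3_class(br, "rme_significance")
  expect_equal(br$gene_identity_bits, 3 * log2(500))
  expect_equal(br$sample_count_bits, 30 * log_star(3))
  expect_equal(br$gene_count_bits, 3 * log_star(30))
  expect_equal(br$d, br$d_prime - br$gene_identity_bits -
                 br$sample_count_bits - br$gene_count_bits - br$sort_bits)
  expect_equal(br$significance, if (br$d > 0) 2^(-br$d) else 1)
  expect_true(br$significance <= 1)
  # all-zero module columns: no compression, significance capped at 1
  x0 <- x; x0[, c("g4", "g5")] <- 0L
  br0 <- d_score(as_mutation_matrix(x0), c("g4", "g5"), n_total = 500)
  expect_lte(br0$d, 0)
  expect_equal(br0$significance, 1)
  expect_error(d_score(x, "g1"), "too small")
  expect_error(d_score(x, c("g1", "g2"), n_total = 5), "n_total")
})

test_that("d is invariant to input ordering of samples and genes", {
  set.seed(31)
  x <- as_mutation_matrix(matrix(rbinom(200, 1, 0.2), 20, 10,
                                 dimnames = list(paste0("s", 1:20),
                                                 paste0("g", 1:10))))
  genes <- c("g2", "g5", "g9")
  b1 <- d_score(x, genes, n_total = 100, p_null = 0.05)
  xp <- as_mutation_matrix(x[sample(20), sample(10)], n_total = 10)
  b2 <- d_score(xp, rev(genes), n_total = 100, p_null = 0.05)
  expect_equal(b2$d, b1$d, tolerance = 1e-12)
})

test_that("d grows with both coverage and exclusivity", {
  pn <- 13.38 / 1290
  score <- function(cv, ex) {
    m <- equal_module_matrix(coverage = cv, exclusivity = ex)
    d_score(m, colnames(m), n_total = 1290, p_null = pn)$d
  }
  expect_gt(score(1, 1), score(0.7, 1))
  expect_gt(score(0.8, 1), score(0.8, 0.6))
})
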