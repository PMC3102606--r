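test_that("matrix text round trip is the identity, including degenerate shapes", {
  set.seed(41)
  shapes <- list(c(2, 2), c(1, 1), c(5, 8), c(3, 1), c(4, 0))
  for (sh in shapes) {
    x <- matrix(rbinom(sh[1] * sh[2], 1, 0.4), sh[1], sh[2],
                dimnames = list(sprintf("s%d", seq_len(sh[1])),
                                if (sh[2]) sprintf("gene%d", seq_len(sh[2]))
                                else character(0)))
    x <- as_mutation_matrix(x)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_mutation_matrix(x, path)
    y <- read_mutation_matrix(path)
    expect_identical(unname(unclass(y))[, ], unname(unclass(x))[, ])
    expect_identical(dimnames(y), dimnames(x))
    # writing the re-read matrix reproduces the file byte for byte
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_mutation_matrix(y, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("diagonal two-sample file parses to the expected cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgA\tgB", "s1\t1\t0", "s2\t0\t1"), path)
  x <- read_mutation_matrix(path)
  expect_equal(sum(x), 2)
  expect_equal(diag(unclass(x)[, ]), c(s1 = 1L, s2 = 1L), ignore_attr = TRUE)
  expect_equal(x["s1", "gA"] + x["s2", "gB"], 2L)
})

test_that("malformed values and duplicate labels are rejected with location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgA\tgB", "s1\t1\t2"), path)
  expect_error(read_mutation_matrix(path), "invalid value '2'.*gB")
  writeLines(c("sample\tgA\tgA", "s1\t1\t0"), path)
  expect_error(read_mutation_matrix(path), "duplicate gene")
  writeLines(c("sample\tgA", "s1\t1", "s1\t0"), path)
  expect_error(read_mutation_matrix(path), "duplicate sample")
  expect_error(as_mutation_matrix(matrix(2, 1, 1,
                                         dimnames = list("s1", "g1"))),
               "non-binary")
})

test_that("merge_calls keeps validated non-synonymous points and all CNAs", {
  samples <- c("s1", "s2", "s3"); genes <- c("gA", "gB")
  pc <- data.frame(sample = c("s1", "s1", "s2"), gene = c("gA", "gB", "gA"),
                   validated = c(TRUE, TRUE, FALSE),
                   synonymous = c(FALSE, TRUE, FALSE))
  cc <- data.frame(sample = c("s1", "s2"), gene = c("gA", "gB"),
                   direction = c("amp", "del"))
  x <- merge_calls(pc, cc, samples, genes)
  # s1/gA has both a point call and an amplification: still a single 1
  expect_equal(x["s1", "gA"], 1L)
  # synonymous and non-validated point calls are dropped
  expect_equal(x["s1", "gB"], 0L)
  expect_equal(x["s2", "gA"], 0L)
  expect_equal(x["s2", "gB"], 1L)
  expect_equal(sum(x), 2)
  # only a synonymous call: matrix is empty
  x0 <- merge_calls(data.frame(sample = "s1", gene = "gA", validated = TRUE,
                               synonymous = TRUE), NULL, samples, genes)
  expect_equal(sum(x0), 0)
})

test_that("merge_calls is invariant to call order and duplication", {
  samples <- paste0("s", 1:4); genes <- paste0("g", 1:3)
  pc <- data.frame(sample = c("s1", "s2", "s4"), gene = c("g1", "g2", "g3"),
                   validated = TRUE, synonymous = FALSE)
  cc <- data.frame(sample = c("s3", "s1"), gene = c("g2", "g1"),
                   direction = c("del", "amp"))
  x1 <- merge_calls(pc, cc, samples, genes)
  x2 <- merge_calls(pc[c(3, 1, 2, 2, 1), ], cc[c(2, 1, 1), ], samples, genes)
  expect_identical(x1, x2)
})

test_that("calls referencing unknown samples or genes are a hard error", {
  pc <- data.frame(sample = "sX", gene = "gA", validated = TRUE,
                   synonymous = FALSE)
  expect_error(merge_calls(pc, NULL, c("s1"), c("gA")), "unknown.*sX")
  cc <- data.frame(sample = "s1", gene = "gZ", direction = "amp")
  expect_error(merge_calls(NULL, cc, c("s1"), c("gA")), "unknown.*gZ")
  cc2 <- data.frame(sample = "s1", gene = "gA", direction = "gain")
  expect_error(merge_calls(NULL, cc2, c("s1"), c("gA")), "direction")
})

test_that("call-file readers accept plain and MAF-style columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol\tValidation_Status\tVariant_Classification",
               "s1\tTP53\tValid\tMissense_Mutation",
               "s2\tTP53\tValid\tSilent"), path)
  pc <- read_point_calls(path)
  expect_equal(pc$validated, c(TRUE, TRUE))
  expect_equal(pc$synonymous, c(FALSE, TRUE))
  writeLines(c("sample\tgene\tdirection", "s1\tMDM2\tamp"), path)
  cc <- read_cna_calls(path)
  expect_equal(cc$direction, "amp")
})

test_that("recurrence filter is inclusive, idempotent and monotone", {
  set.seed(7)
  # k=10: a single altered sample meets a 10% threshold (boundary inclusive)
  x <- bin_matrix(c("100", "000", "000", "000", "000",
                    "010", "010", "000", "000", "000"))
  f <- filter_recurrent(x, 0.10)
  expect_setequal(colnames(f), c("g1", "g2"))  # g3 has zero aberrations
  expect_equal(attr(f, "n_total"), 3L)
  # k=20 with column frequencies 0.05, 0.10, 0.30
  x2 <- as_mutation_matrix(matrix(
    c(rep(1, 1), rep(0, 19), rep(1, 2), rep(0, 18), rep(1, 6), rep(0, 14)),
    20, 3, dimnames = list(paste0("s", 1:20), paste0("g", 1:3))))
  expect_equal(ncol(filter_recurrent(x2, 0.10)), 2)
  # idempotence and monotonicity over random matrices
  for (i in 1:5) {
    x3 <- as_mutation_matrix(matrix(rbinom(200, 1, runif(1, 0.05, 0.3)),
                                    20, 10,
                                    dimnames = list(paste0("s", 1:20),
                                                    paste0("g", 1:10))))
    f1 <- filter_recurrent(x3, 0.15)
    expect_identical(filter_recurrent(f1, 0.15), f1)
    expect_true(all(colnames(filter_recurrent(x3, 0.25)) %in% colnames(f1)))
    expect_equal(attr(f1, "n_total"), 10L)
  }
})

test_that("coverage and exclusivity match a per-sample counting oracle", {
  x <- bin_matrix(c("10", "10", "01", "00"), genes = c("gA", "gB"))
  expect_equal(module_coverage(x, c("gA", "gB")), 0.75)
  expect_equal(module_exclusivity(x, c("gA", "gB")), 1)
  x2 <- bin_matrix(c("11", "10", "00"))
  expect_equal(module_exclusivity(x2, c("g1", "g2")), 0.5)
  # single-gene module is always fully exclusive
  expect_equal(module_exclusivity(x2, "g1"), 1)
  # all-zero module: coverage 0, exclusivity undefined
  x3 <- bin_matrix(c("00", "00"))
  expect_equal(module_coverage(x3, c("g1", "g2")), 0)
  expect_error(module_exclusivity(x3, c("g1", "g2")), "undefined")
  expect_error(module_coverage(x, "nope"), "unknown gene")
  # property: brute-force per-sample counts on random matrices
  set.seed(11)
  for (i in 1:10) {
    m <- as_mutation_matrix(matrix(rbinom(60, 1, 0.35), 10, 6,
                                   dimnames = list(paste0("s", 1:10),
                                                   paste0("g", 1:6))))
    genes <- sample(colnames(m), sample(2:4, 1))
    counts <- apply(m[, genes, drop = FALSE], 1, sum)
    expect_equal(module_coverage(m, genes), mean(counts >= 1))
    if (any(counts >= 1))
      expect_equal(module_exclusivity(m, genes),
                   sum(counts == 1) / sum(counts >= 1))
  }
})
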