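#' Validate a binary mutation matrix
#'
#' A mutation matrix is a samples-by-genes integer matrix with entries in
#' \{0, 1\}, unique row (sample) names and unique column (gene) names. It is
#' the central data object: `x[i, j] == 1` records an aberration (point
#' mutation or copy-number alteration) of gene `j` in sample `i`.
#'
#' @param x matrix-like object with dimnames.
#' @param n_total optional count of genes assayed before any recurrence
#'   filtering; recorded as attribute `n_total` and used later in the
#'   gene-identity penalty of the significance test. Defaults to a
#'   pre-existing `n_total` attribute, else `ncol(x)`.
#' @return the validated integer matrix (invisibly classed as a plain matrix)
#'   with attribute `n_total`.
#' @export
as_mutation_matrix <- function(x, n_total = NULL) {
  x <- as.matrix(x)
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x))))
    stop("mutation matrix must have sample (row) and gene (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  storage.mode(x) <- "integer"
  bad <- which(!(x == 0L | x == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary entry at sample '%s', gene '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  attr(x, "n_total") <- as.integer(n_total %||% attr(x, "n_total") %||% ncol(x))
  x
}

#' Read a mutation matrix from tab-separated text
#'
#' Expected layout: a header row of gene labels (optionally preceded by a
#' label for the sample column), then one row per sample consisting of the
#' sample label followed by 0/1 cells, all tab-separated.
#'
#' @param path file path.
#' @return a validated mutation matrix (see [as_mutation_matrix()]).
#' @export
read_mutation_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  if (length(body) == 0) {
    genes <- if (length(header) > 0 && header[1] %in% c("", "sample"))
      header[-1] else header
    m <- matrix(integer(0), nrow = 0, ncol = length(genes),
                dimnames = list(character(0), genes))
    return(as_mutation_matrix(m))
  }
  nb <- lengths(body)
  if (length(unique(nb)) != 1)
    stop("ragged rows in ", path, ": differing field counts")
  genes <- if (nb[1] == length(header)) header[-1]
           else if (nb[1] == length(header) + 1) header
           else stop("header/body field count mismatch in ", path)
  samples <- vapply(body, `[`, character(1), 1L)
  vals <- lapply(body, function(f) f[-1])
  for (i in seq_along(vals)) {
    bad <- which(!(vals[[i]] %in% c("0", "1")))
    if (length(bad) > 0)
      stop(sprintf("invalid value '%s' at sample '%s', gene '%s'",
                   vals[[i]][bad[1]], samples[i], genes[bad[1]]))
  }
  m <- matrix(as.integer(unlist(vals)), nrow = length(body),
              ncol = length(genes), byrow = TRUE,
              dimnames = list(samples, genes))
  as_mutation_matrix(m)
}

#' Write a mutation matrix as tab-separated text
#'
#' Inverse of [read_mutation_matrix()]: a `sample` header column, gene labels
#' across the header row, 0/1 cells.
#'
#' @param x mutation matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(x, path) {
  x <- as_mutation_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(x)), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- apply(x, 1L, paste, collapse = "\t")
    writeLines(paste(rownames(x), body, sep = if (ncol(x)) "\t" else ""), con)
  }
  invisible(path)
}

#' Merge gene-level aberration calls into a mutation matrix
#'
#' Point-mutation calls are retained only when validated and non-synonymous;
#' copy-number calls (amplification or deletion) are always retained and the
#' direction is not encoded. A cell is 1 if at least one retained call exists
#' for that sample/gene; duplicated calls and call order have no effect.
#'
#' @param point_calls data frame with columns `sample`, `gene`, `validated`
#'   (logical), `synonymous` (logical); may be `NULL` or empty.
#' @param cna_calls data frame with columns `sample`, `gene`, `direction`
#'   (`"amp"` or `"del"`); may be `NULL` or empty.
#' @param samples,genes the full sample and gene universes; calls referencing
#'   labels outside these are an error (silent unions would corrupt the
#'   sample count).
#' @return mutation matrix over `samples` x `genes`.
#' @export
merge_calls <- function(point_calls, cna_calls, samples, genes) {
  if (anyDuplicated(samples) || anyDuplicated(genes))
    stop("sample and gene universes must be free of duplicates")
  x <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  check_known <- function(calls, what) {
    bad_s <- setdiff(unique(calls$sample), samples)
    bad_g <- setdiff(unique(calls$gene), genes)
    if (length(bad_s) || length(bad_g))
      stop(what, " reference unknown labels: ",
           paste(c(bad_s, bad_g), collapse = ", "))
  }
  if (!is.null(point_calls) && nrow(point_calls) > 0) {
    check_known(point_calls, "point calls")
    keep <- point_calls$validated & !point_calls$synonymous
    pc <- point_calls[keep, , drop = FALSE]
    if (nrow(pc) > 0) x[cbind(pc$sample, pc$gene)] <- 1L
  }
  if (!is.null(cna_calls) && nrow(cna_calls) > 0) {
    check_known(cna_calls, "CNA calls")
    bad <- setdiff(unique(cna_calls$direction), c("amp", "del"))
    if (length(bad)) stop("unknown CNA direction: ", paste(bad, collapse = ", "))
    x[cbind(cna_calls$sample, cna_calls$gene)] <- 1L
  }
  as_mutation_matrix(x)
}

#' Read point-mutation calls from tab-separated text
#'
#' Accepts either plain column names (`sample`, `gene`, `validation_status`,
#' `variant_classification`) or their MAF equivalents
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Validation_Status`,
#' `Variant_Classification`).
#'
#' @param path file path.
#' @return data frame with columns `sample`, `gene`, `validated`,
#'   `synonymous`, suitable for [merge_calls()].
#' @export
read_point_calls <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(d)) return(d[[nm]])
    stop("missing column (one of): ", paste(c(...), collapse = ", "))
  }
  data.frame(
    sample = as.character(pick("sample", "Tumor_Sample_Barcode")),
    gene = as.character(pick("gene", "Hugo_Symbol")),
    validated = tolower(pick("validation_status", "Validation_Status")) %in%
      c("valid", "validated", "true", "1"),
    synonymous = tolower(pick("variant_classification", "Variant_Classification")) %in%
      c("silent", "synonymous", "synonymous_variant"),
    stringsAsFactors = FALSE
  )
}

#' Read gene-level copy-number calls from tab-separated text
#'
#' @param path file path to a TSV with columns `sample`, `gene`, `direction`
#'   (`amp`/`del`).
#' @return data frame suitable for [merge_calls()].
#' @export
read_cna_calls <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "direction")
  if (!all(need %in% names(d)))
    stop("CNA call file needs columns: ", paste(need, collapse = ", "))
  data.frame(sample = as.character(d$sample), gene = as.character(d$gene),
             direction = tolower(as.character(d$direction)),
             stringsAsFactors = FALSE)
}

#' Keep only recurrently altered genes
#'
#' Genes altered in fewer than `min_frequency` of samples carry too little
#' signal for exclusivity scoring and are dropped. The comparison is
#' inclusive (frequency >= threshold) and operates on frequencies, not
#' counts. The original pre-filter gene count is carried along as the
#' `n_total` attribute so that the significance test's gene-identity penalty
#' reflects the full universe searched.
#'
#' @param x mutation matrix.
#' @param min_frequency fraction in (0, 1].
#' @return filtered mutation matrix (samples unchanged).
#' @export
filter_recurrent <- function(x, min_frequency) {
  x <- as_mutation_matrix(x)
  if (!(min_frequency > 0 && min_frequency <= 1))
    stop("min_frequency must lie in (0, 1]")
  n_total <- attr(x, "n_total")
  keep <- colMeans(x) >= min_frequency
  as_mutation_matrix(x[, keep, drop = FALSE], n_total = n_total)
}

check_genes <- function(x, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("empty gene set")
  missing <- setdiff(genes, colnames(x))
  if (length(missing))
    stop("unknown genes: ", paste(missing, collapse = ", "))
  genes
}

#' Module coverage
#'
#' Fraction of samples carrying at least one aberration among the module's
#' genes.
#'
#' @param x mutation matrix.
#' @param genes character vector of module gene labels.
#' @return fraction in \[0, 1\].
#' @export
module_coverage <- function(x, genes) {
  x <- as_mutation_matrix(x)
  genes <- check_genes(x, genes)
  if (nrow(x) == 0) stop("matrix has no samples")
  sum(rowSums(x[, genes, drop = FALSE]) >= 1) / nrow(x)
}

#' Module exclusivity
#'
#' Among samples covered by the module (at least one aberration), the
#' fraction carrying exactly one aberration. Undefined (an error) when no
#' sample is covered.
#'
#' @inheritParams module_coverage
#' @return fraction in \[0, 1\].
#' @export
module_exclusivity <- function(x, genes) {
  x <- as_mutation_matrix(x)
  genes <- check_genes(x, genes)
  rs <- rowSums(x[, genes, drop = FALSE])
  covered <- sum(rs >= 1)
  if (covered == 0) stop("exclusivity undefined: no sample covers the module")
  sum(rs == 1) / covered
}
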