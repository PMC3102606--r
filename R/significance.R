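#' Configuration of the algorithmic significance test
#'
#' @param epsilon probability assigned to an aberration in a cell where the
#'   exclusivity model considers one essentially impossible (a one already
#'   seen in the row, or no unobserved aberrations left for the gene or
#'   sample). Must lie in (0, 0.5); kept small but nonzero to avoid infinite
#'   penalties. The default `NULL` resolves at scoring time to
#'   `1 / (10 * k * m)`, tying the scale to the submatrix size.
#' @param log_star_constant the universal integer-code constant c added (as
#'   `log2(c)`) to the iterated-logarithm code length; the standard value is
#'   2.865064.
#' @param sort_penalty_mode how to charge for transmitting the sorted order
#'   of the module submatrix:
#'   * `"counts"` (default): 0 bits. The per-sample and per-gene aberration
#'     counts are already transmitted and the tie-break (original index,
#'     stable sort) is deterministic, so the decoder reconstructs the sorted
#'     order from the counts alone.
#'   * `"tie_groups"`: `sum(log2(group_size!))` over groups of equal counts,
#'     rows plus columns — the cost of disambiguating within ties.
#'   * `"full_permutation"`: `log2(k!) + log2(m!)`.
#' @return a list of class `significance_config`.
#' @export
significance_config <- function(epsilon = NULL,
                                log_star_constant = 2.865064,
                                sort_penalty_mode = c("counts", "tie_groups",
                                                      "full_permutation")) {
  sort_penalty_mode <- match.arg(sort_penalty_mode)
  if (!is.null(epsilon) && !(epsilon > 0 && epsilon < 0.5))
    stop("epsilon must lie in (0, 0.5)")
  if (!(log_star_constant > 1)) stop("log_star_constant must exceed 1")
  structure(list(epsilon = epsilon, log_star_constant = log_star_constant,
                 sort_penalty_mode = sort_penalty_mode),
            class = "significance_config")
}

#' Iterated-logarithm code length
#'
#' Universal code length (in bits) for a positive integer:
#' `log2(c) + log2(x) + log2(log2(x)) + ...`, summing only the strictly
#' positive terms. Arguments below 1 are a domain error.
#'
#' @param x positive values (vectorised).
#' @param log_star_constant the constant c (> 1).
#' @return code lengths in bits.
#' @export
log_star <- function(x, log_star_constant = 2.865064) {
  if (any(x < 1)) stop("log_star requires x >= 1")
  vapply(x, function(xi) {
    s <- log2(log_star_constant)
    t <- log2(xi)
    while (t > 0) {
      s <- s + t
      t <- log2(t)
    }
    s
  }, numeric(1))
}

#' Background aberration probability
#'
#' The null model assumes aberrations occur independently at a single
#' background frequency: total aberrations divided by cells, equivalently the
#' mean number of aberrant genes per sample divided by the gene count.
#' Estimated on the full (post-filter) matrix handed to discovery; supply a
#' pre-filter estimate via the `p_null` arguments downstream to override.
#'
#' @param x mutation matrix with at least one 0 and one 1.
#' @return probability in (0, 1).
#' @export
background_frequency <- function(x) {
  x <- as_mutation_matrix(x)
  if (length(x) == 0) stop("empty matrix has no background frequency")
  p <- mean(x)
  if (p == 0 || p == 1)
    stop("degenerate background: matrix is all-", if (p == 0) "zero" else "one")
  p
}

# First-difference lexicographic comparison of equal-length numeric keys.
is_lex_greater <- function(a, b) {
  i <- which(a != b)
  length(i) > 0 && a[i[1]] > b[i[1]]
}

# Pack the rows of a binary matrix into numeric keys, 50 columns per chunk,
# leftmost column most significant: lexicographic comparison of packed
# chunks equals lexicographic comparison of the rows.
pack_bits <- function(M) {
  m <- ncol(M)
  if (m == 0) return(matrix(0, nrow(M), 1))
  nch <- ceiling(m / 50)
  out <- matrix(0, nrow(M), nch)
  for (ch in seq_len(nch)) {
    idx <- ((ch - 1) * 50 + 1):min(ch * 50, m)
    out[, ch] <- M[, idx, drop = FALSE] %*% 2^(rev(seq_along(idx)) - 1)
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

#' Canonically sort a module submatrix
#'
#' Rows are ordered by decreasing aberration count, then columns by
#' decreasing count. Ties are resolved canonically: among column orders that
#' respect the count sort (permutations within tie groups), the one whose
#' row-sorted matrix is lexicographically greatest is chosen, with rows
#' tie-broken by their bit patterns. The result therefore depends only on the
#' matrix content, never on the input ordering of samples or genes.
#'
#' @param sub mutation submatrix restricted to the module genes.
#' @param sort_penalty_mode see [significance_config()].
#' @return list with elements `submatrix` (sorted), `sort_bits`, `row_order`,
#'   `col_order`.
#' @export
sort_submatrix <- function(sub, sort_penalty_mode = "counts") {
  if (length(sub) == 0) stop("empty submatrix")
  rs <- rowSums(sub)
  cs <- colSums(sub)
  ckey <- as.vector(rs %*% sub)  # count-weighted, permutation-invariant
  base <- order(-cs, -ckey)
  grp <- paste(cs, ckey)[base]
  row_order_for <- function(co) {
    rn <- pack_bits(sub[, co, drop = FALSE])
    do.call(order, c(list(-rs),
                     lapply(seq_len(ncol(rn)), function(j) -rn[, j])))
  }
  groups <- split(seq_along(base), factor(grp, levels = unique(grp)))
  n_orders <- prod(factorial(lengths(groups)))
  if (n_orders == 1 || n_orders > 720) {
    # no column ties (or pathologically many: keep the signature order)
    co <- base
    ro <- row_order_for(co)
  } else {
    cand <- Reduce(function(acc, g) {
      unlist(lapply(acc, function(pre)
        lapply(all_perms(base[g]), function(p) c(pre, p))),
        recursive = FALSE)
    }, groups, accumulate = FALSE, init = list(integer(0)))
    best <- NULL
    for (co in cand) {
      ro <- row_order_for(co)
      key <- as.vector(t(pack_bits(sub[ro, co, drop = FALSE])))
      if (is.null(best) || is_lex_greater(key, best$key))
        best <- list(co = co, ro = ro, key = key)
    }
    co <- best$co
    ro <- best$ro
  }
  tie_bits <- function(counts) {
    sum(vapply(table(counts), function(g) lfactorial(g) / log(2), numeric(1)))
  }
  sort_bits <- switch(sort_penalty_mode,
    counts = 0,
    tie_groups = tie_bits(rs) + tie_bits(cs),
    full_permutation = (lfactorial(length(rs)) + lfactorial(length(cs))) / log(2),
    stop("unknown sort_penalty_mode: ", sort_penalty_mode)
  )
  list(submatrix = sub[ro, co, drop = FALSE], sort_bits = sort_bits,
       row_order = ro, col_order = co)
}

#' Per-cell aberration probability under the exclusivity model
#'
#' The model expects each sample to carry a single aberration within the
#' module: if the row has not yet shown a one and both the gene and the
#' sample still have unobserved aberrations, the one lands on this gene with
#' probability proportional to the gene's remaining count among the row's
#' unobserved cells; otherwise the probability collapses to `epsilon`. The
#' result is clamped into `[epsilon, 1 - epsilon]` so both outcomes always
#' have positive probability.
#'
#' @param gene_remaining unobserved aberration count of the current gene.
#' @param sample_remaining unobserved aberration count of the current sample.
#' @param row_has_one has a one already been observed in this row?
#' @param row_remaining_total sum of unobserved gene counts over this row's
#'   unobserved cells (current cell included).
#' @param epsilon the low-probability floor.
#' @return probability that the current cell is 1.
#' @export
rme_cell_probability <- function(gene_remaining, sample_remaining, row_has_one,
                                 row_remaining_total, epsilon) {
  if (row_has_one || gene_remaining <= 0 || sample_remaining <= 0)
    return(epsilon)
  min(max(gene_remaining / row_remaining_total, epsilon), 1 - epsilon)
}

#' Encoding gain of a sorted module submatrix
#'
#' Scans the sorted submatrix row by row, left to right, encoding each cell
#' under the exclusivity model ([rme_cell_probability()]) and under the null
#' (independent aberrations at `p_null`), and accumulates the per-cell
#' log2-likelihood ratio. Positive values mean the exclusivity model
#' compresses the submatrix relative to the null.
#'
#' @param sub sorted submatrix (see [sort_submatrix()]).
#' @param p_null background aberration probability in (0, 1).
#' @param config a [significance_config()]; its `epsilon` (or the size-based
#'   default) is the low-probability floor.
#' @return the gain d' in bits.
#' @export
encoding_gain <- function(sub, p_null, config = significance_config()) {
  if (length(sub) == 0) return(0)
  if (!(p_null > 0 && p_null < 1)) stop("p_null must lie in (0, 1)")
  eps <- config$epsilon %||% (1 / (10 * nrow(sub) * ncol(sub)))
  storage.mode(sub) <- "integer"
  .encoding_gain_cpp(sub, p_null, eps)
}

significance_from_d <- function(d) ifelse(d > 0, 2^(-d), 1)

#' Algorithmic significance of a gene module
#'
#' Compression-based (minimum description length) significance test. The
#' module submatrix is canonically sorted and encoded under the exclusivity
#' model; from the resulting gain d' the description penalties are
#' subtracted: `m*log2(n_total)` bits to name the module genes out of the
#' full universe (an implicit multiple-testing correction), `k*log*(m)` and
#' `m*log*(k)` bits for the per-sample and per-gene aberration counts, and
#' the sorted-order bits per `sort_penalty_mode`. The significance of the
#' remaining saving `d` is `2^-d`, capped at 1 when `d <= 0`.
#'
#' @param x mutation matrix (the full post-filter matrix; used for the
#'   background frequency and the sample count k).
#' @param genes module gene set (at least 2 genes).
#' @param n_total gene universe size before recurrence filtering; defaults to
#'   the matrix's `n_total` attribute, else `ncol(x)`.
#' @param config a [significance_config()].
#' @param p_null optional override of the background probability (e.g. an
#'   estimate from the unfiltered call set).
#' @return object of class `rme_significance`: a list with `d_prime`, the
#'   penalty terms, `d`, `significance`, `p_null`, `epsilon`, `genes`, `k`,
#'   `m`, `n_total`.
#' @export
d_score <- function(x, genes, n_total = NULL, config = significance_config(),
                    p_null = NULL) {
  x <- as_mutation_matrix(x)
  genes <- check_genes(x, genes)
  if (length(genes) < 2)
    stop("module too small: significance needs at least 2 genes")
  n_total <- as.integer(n_total %||% attr(x, "n_total") %||% ncol(x))
  if (n_total < ncol(x)) stop("n_total cannot be below the matrix gene count")
  p_null <- p_null %||% background_frequency(x)
  d_score_impl(x, genes, n_total, config, p_null)
}

# validation-free scoring core shared with score_candidates()
d_score_impl <- function(x, genes, n_total, config, p_null) {
  m <- length(genes)
  k <- nrow(x)
  eps <- config$epsilon %||% (1 / (10 * k * m))
  srt <- sort_submatrix(x[, genes, drop = FALSE], config$sort_penalty_mode)
  d_prime <- .encoding_gain_cpp(srt$submatrix, p_null, eps)
  gene_identity_bits <- m * log2(n_total)
  sample_count_bits <- k * log_star(m, config$log_star_constant)
  gene_count_bits <- m * log_star(k, config$log_star_constant)
  d <- d_prime - gene_identity_bits - sample_count_bits - gene_count_bits -
    srt$sort_bits
  structure(list(
    d_prime = d_prime,
    gene_identity_bits = gene_identity_bits,
    sample_count_bits = sample_count_bits,
    gene_count_bits = gene_count_bits,
    sort_bits = srt$sort_bits,
    d = d,
    significance = significance_from_d(d),
    p_null = p_null,
    epsilon = eps,
    genes = sort(genes),
    k = k, m = m, n_total = n_total
  ), class = "rme_significance")
}

#' @export
print.rme_significance <- function(x, ...) {
  cat("Algorithmic significance of module {",
      paste(x$genes, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  encoding gain d': %.2f bits (p_null = %.5f)\n",
              x$d_prime, x$p_null))
  cat(sprintf("  penalties: gene identity %.2f + sample counts %.2f + gene counts %.2f + sort %.2f\n",
              x$gene_identity_bits, x$sample_count_bits, x$gene_count_bits,
              x$sort_bits))
  cat(sprintf("  d = %.2f bits, significance 2^-d = %.3g\n",
              x$d, x$significance))
  invisible(x)
}
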