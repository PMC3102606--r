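# Build a small mutation matrix from row strings like "101".
bin_matrix <- function(rows, genes = NULL, samples = NULL) {
  vals <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  genes <- genes %||% paste0("g", seq_len(ncol(vals)))
  samples <- samples %||% paste0("s", seq_len(nrow(vals)))
  dimnames(vals) <- list(samples, genes)
  as_mutation_matrix(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent reference implementation of the row-major encoding gain,
# written directly from the coding rules with explicit state, and asserting
# the count-conservation invariant at every step.
ref_encoding_gain <- function(sub, p_null, eps) {
  k <- nrow(sub); m <- ncol(sub)
  a <- colSums(sub)          # per-gene unobserved counts
  b <- rowSums(sub)          # per-sample unobserved counts
  d <- 0
  for (i in seq_len(k)) {
    seen <- FALSE
    for (j in seq_len(m)) {
      stopifnot(sum(a) == sum(b))  # conservation of remaining mutations
      denom <- sum(a[j:m])
      p1 <- if (seen || a[j] == 0 || b[i] == 0) eps
            else min(max(a[j] / denom, eps), 1 - eps)
      if (sub[i, j] == 1) {
        d <- d + log2(p1 / p_null)
        a[j] <- a[j] - 1; b[i] <- b[i] - 1; seen <- TRUE
      } else {
        d <- d + log2((1 - p1) / (1 - p_null))
      }
    }
  }
  d
}

# 100 x m module submatrix with given coverage and exclusivity, aberrations
# distributed equally across genes (covered samples beyond the exclusive
# ones carry a second aberration in the next gene round-robin).
equal_module_matrix <- function(k = 100, m = 3, coverage = 1, exclusivity = 1) {
  ncov <- round(coverage * k)
  nex <- round(exclusivity * ncov)
  x <- matrix(0L, k, m,
              dimnames = list(sprintf("s%03d", seq_len(k)),
                              paste0("g", seq_len(m))))
  g <- rep_len(seq_len(m), ncov)
  for (i in seq_len(ncov)) x[i, g[i]] <- 1L
  if (ncov > nex)
    for (i in seq(nex + 1, ncov)) x[i, (g[i] %% m) + 1L] <- 1L
  as_mutation_matrix(x)
}

# Brute-force enumeration of connected vertex sets containing `seed`:
# check every subset for connectivity of the induced subgraph.
brute_connected_sets <- function(graph, seed, max_size) {
  vs <- igraph::V(graph)$name
  out <- list()
  for (sz in 2:min(max_size, length(vs))) {
    for (cmb in utils::combn(vs, sz, simplify = FALSE)) {
      if (!(seed %in% cmb)) next
      sub <- igraph::induced_subgraph(graph, cmb)
      if (igraph::is_connected(sub)) out[[length(out) + 1L]] <- sort(cmb)
    }
  }
  out
}

set_key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))
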