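#' Discovery pipeline configuration
#'
#' @param min_recurrence recurrence filter threshold (fraction of samples,
#'   inclusive). The default 0.10 is the conservative choice used for the
#'   glioblastoma-scale analyses.
#' @param max_module_size largest module searched for (inclusive, >= 2).
#' @param d_threshold minimum compression gain d (bits) for a module to be
#'   reported; 50 bits corresponds to significance 2^-50 (about 8.9e-16).
#'   A sensible threshold grows with the size of the input data.
#' @param winnow a [winnow_config()].
#' @param significance a [significance_config()].
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(min_recurrence = 0.10, max_module_size = 5,
                             d_threshold = 50, winnow = winnow_config(),
                             significance = significance_config()) {
  if (!(max_module_size >= 2)) stop("max_module_size must be >= 2")
  if (!(d_threshold > 0)) stop("d_threshold must be positive")
  structure(list(min_recurrence = min_recurrence,
                 max_module_size = as.integer(max_module_size),
                 d_threshold = d_threshold,
                 winnow = winnow, significance = significance),
            class = "discovery_config")
}

#' Enumerate connected gene sets containing a seed
#'
#' All gene sets of size 2..`max_size` that contain `seed` and induce a
#' connected subgraph of the exclusivity graph, found by breadth-first growth
#' (every connected superset of the seed is reachable by adding one adjacent
#' gene at a time). Sets are canonicalised by sorted gene labels; the output
#' order is deterministic.
#'
#' @param graph igraph from [prune_to_graph()].
#' @param seed gene label present in the graph.
#' @param max_size inclusive size limit.
#' @return list of character vectors (sorted gene sets); empty for an
#'   isolated seed.
#' @export
enumerate_connected <- function(graph, seed, max_size) {
  vs <- igraph::V(graph)$name
  if (!(seed %in% vs)) stop("seed gene not in graph: ", seed)
  adj <- lapply(igraph::adjacent_vertices(graph, vs), function(v) sort(v$name))
  names(adj) <- vs
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 0)
  queue <- list(seed)
  head_i <- 1L
  while (head_i <= length(queue)) {
    s <- queue[[head_i]]; head_i <- head_i + 1L
    nbrs <- setdiff(sort(unique(unlist(adj[s], use.names = FALSE))), s)
    for (u in nbrs) {
      s2 <- sort(c(s, u))
      key <- paste(s2, collapse = "\r")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- s2
      if (length(s2) < max_size) queue[[length(queue) + 1L]] <- s2
    }
  }
  out
}

# All connected gene sets of size 2..max_size, each exactly once: for every
# anchor vertex v, grow sets whose smallest member is v by adding adjacent
# vertices with larger id (any connected set is reachable this way by
# repeatedly removing a spanning-tree leaf other than the anchor).
all_connected_sets <- function(graph, max_size) {
  nv <- igraph::vcount(graph)
  nms <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, seq_len(nv)), as.integer)
  out <- list()
  n_out <- 0L
  for (v in seq_len(nv)) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    queue <- list(v)
    head_i <- 1L
    while (head_i <= length(queue)) {
      s <- queue[[head_i]]; head_i <- head_i + 1L
      if (length(s) >= max_size) next
      nb <- unique(unlist(adj[s], use.names = FALSE))
      nb <- nb[nb > v & !(nb %in% s)]
      for (u in nb) {
        pos <- findInterval(u, s)
        s2 <- append(s, u, after = pos)
        key <- paste(s2, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        n_out <- n_out + 1L
        out[[n_out]] <- s2
        queue[[length(queue) + 1L]] <- s2
      }
    }
  }
  lapply(out, function(s) nms[s])
}

#' Score candidate modules and keep the significant ones
#'
#' Deduplicates candidate gene sets (the same set is typically reached from
#' several seeds), scores each with [d_score()], and retains those with
#' `d >= d_threshold`.
#'
#' @param x mutation matrix (post-filter).
#' @param candidates list of gene sets from [enumerate_connected()].
#' @param n_total pre-filter gene universe size.
#' @param config a [discovery_config()].
#' @param p_null optional background probability override (computed once from
#'   `x` when `NULL`).
#' @return list of candidate-module records: `genes`, `coverage`,
#'   `exclusivity`, `covered_samples`, `breakdown` (the `rme_significance`),
#'   `d`, `significance`.
#' @export
score_candidates <- function(x, candidates, n_total = NULL,
                             config = discovery_config(), p_null = NULL) {
  if (length(candidates) == 0) return(list())
  x <- as_mutation_matrix(x)
  p_null <- p_null %||% background_frequency(x)
  n_total <- as.integer(n_total %||% attr(x, "n_total") %||% ncol(x))
  sets <- unique(lapply(candidates, function(g) sort(as.character(g))))
  # cheap exact upper bound on d: every 1 gains at most log2((1-eps)/p_null)
  # bits, every 0 at most log2((1-eps)/(1-p_null)); candidates that cannot
  # reach the threshold are skipped without encoding
  k <- nrow(x)
  cs_all <- colSums(x)
  sig <- config$significance
  sizes <- sort(unique(lengths(sets)))
  bound <- lapply(sizes, function(m) {
    eps <- sig$epsilon %||% (1 / (10 * k * m))
    list(g1 = log2((1 - eps) / p_null),
         g0 = log2((1 - eps) / (1 - p_null)),
         pen = m * log2(n_total) + k * log_star(m, sig$log_star_constant) +
           m * log_star(k, sig$log_star_constant))
  })
  names(bound) <- sizes
  out <- list()
  for (genes in sets) {
    m <- length(genes)
    b <- bound[[as.character(m)]]
    n1 <- sum(cs_all[genes])
    if (n1 * b$g1 + (k * m - n1) * b$g0 - b$pen < config$d_threshold) next
    br <- d_score_impl(x, genes, n_total, sig, p_null)
    if (br$d < config$d_threshold) next
    rs <- rowSums(x[, genes, drop = FALSE])
    covered <- sum(rs >= 1)
    out[[length(out) + 1L]] <- list(
      genes = genes,
      coverage = covered / nrow(x),
      exclusivity = if (covered > 0) sum(rs == 1) / covered else NA_real_,
      covered_samples = covered,
      breakdown = br,
      d = br$d,
      significance = br$significance
    )
  }
  out
}

#' Select a disjoint final module set
#'
#' Candidates are binned by gene-set size; repeatedly, among the remaining
#' candidates of the largest size, the one with the highest d is emitted
#' (ties broken by lexicographically smallest sorted gene list) and every
#' remaining candidate sharing a gene with it is discarded.
#'
#' @param scored list of candidate-module records from [score_candidates()].
#' @return the emitted records, in emission order (pairwise gene-disjoint).
#' @export
select_disjoint <- function(scored) {
  out <- list()
  remaining <- scored
  while (length(remaining) > 0) {
    sizes <- vapply(remaining, function(m) length(m$genes), integer(1))
    idx <- which(sizes == max(sizes))
    ds <- vapply(remaining[idx], `[[`, numeric(1), "d")
    best <- idx[ds == max(ds)]
    if (length(best) > 1) {
      keys <- vapply(remaining[best],
                     function(m) paste(m$genes, collapse = "\r"), character(1))
      best <- best[order(keys)][1]
    }
    pick <- remaining[[best]]
    out[[length(out) + 1L]] <- pick
    remaining <- Filter(function(m) !any(m$genes %in% pick$genes), remaining)
  }
  out
}

#' Run the full module-discovery pipeline
#'
#' filter by recurrence -> Winnow edge scoring -> second-highest-weight
#' pruning -> exhaustive connected-subgraph enumeration from every gene ->
#' algorithmic significance scoring -> size-binned disjoint selection. Fully
#' deterministic given the matrix and configuration.
#'
#' @param x mutation matrix.
#' @param n_total pre-filter gene universe size (defaults to the matrix's
#'   `n_total` attribute, else its gene count).
#' @param config a [discovery_config()].
#' @return an object of class `rme`; see [rme()].
#' @export
run_discovery <- function(x, n_total = NULL, config = discovery_config()) {
  x <- as_mutation_matrix(x)
  n_total <- as.integer(n_total %||% attr(x, "n_total") %||% ncol(x))
  # genome-wide background rate, estimated before the recurrence filter:
  # the null model describes aberrations across the whole assayed universe,
  # not just the recurrently altered genes handed to the search
  p_null <- background_frequency(x)
  xf <- filter_recurrent(x, config$min_recurrence)
  res <- list(call = sys.call(), config = config, n_total = n_total,
              k = nrow(x), n_filtered = ncol(xf),
              graph = NULL, n_candidates = 0L, modules = list())
  if (ncol(xf) < 2) {
    warning("fewer than 2 genes survive the recurrence filter; no modules searched")
    class(res) <- "rme"
    return(res)
  }
  W <- score_edges(xf, config$winnow)
  graph <- prune_to_graph(W)
  cand <- all_connected_sets(graph, config$max_module_size)
  scored <- score_candidates(xf, cand, n_total = n_total, config = config,
                             p_null = p_null)
  selected <- select_disjoint(scored)
  res$graph <- graph
  res$n_candidates <- length(cand)
  res$p_null <- p_null
  # all candidates above threshold, before disjoint selection (overlapping
  # sets included) -- the raw detection list the final report is culled from
  res$scored <- scored
  res$modules <- selected
  class(res) <- "rme"
  res
}
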