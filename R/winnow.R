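#' Winnow training configuration
#'
#' @param alpha multiplicative promotion/demotion factor (> 1).
#' @param threshold_fraction the firing threshold is this fraction of the
#'   feature count.
#' @param epochs training passes over the samples (visited in input order,
#'   keeping the whole procedure deterministic).
#' @return list of class `winnow_config`.
#' @export
winnow_config <- function(alpha = 2, threshold_fraction = 0.5, epochs = 10) {
  if (!(alpha > 1)) stop("alpha must exceed 1")
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop("threshold_fraction must lie in (0, 1]")
  if (!(epochs >= 1)) stop("epochs must be >= 1")
  structure(list(alpha = alpha, threshold_fraction = threshold_fraction,
                 epochs = as.integer(epochs)), class = "winnow_config")
}

#' Pairwise mutual exclusivity of two genes
#'
#' Samples where exactly one of the pair is mutated, divided by samples where
#' at least one is mutated. Provided for diagnostics; the discovery pipeline
#' scores exclusivity with Winnow instead because the dense all-pairs network
#' is too large and too densely connected to search.
#'
#' @param x mutation matrix.
#' @param pair two gene labels.
#' @return fraction in \[0, 1\].
#' @export
pairwise_exclusivity <- function(x, pair) {
  x <- as_mutation_matrix(x)
  pair <- check_genes(x, pair)
  if (length(pair) != 2) stop("pair must contain exactly 2 distinct genes")
  rs <- rowSums(x[, pair, drop = FALSE])
  any_mut <- sum(rs >= 1)
  if (any_mut == 0) stop("exclusivity undefined: no sample covers the pair")
  sum(rs == 1) / any_mut
}

#' Train a Winnow2 linear-threshold classifier
#'
#' Mistake-driven online learning: weights start at 1; the learner predicts 1
#' when the summed weight of active features reaches the threshold
#' `threshold_fraction * ncol(features)`; on a false negative the active
#' weights are multiplied by `alpha`, on a false positive divided by `alpha`.
#' Weights therefore stay strictly positive.
#'
#' @param features binary matrix, samples x features.
#' @param labels binary vector, one per sample.
#' @param config a [winnow_config()].
#' @return numeric vector of final feature weights (named when `features`
#'   has column names).
#' @export
winnow_fit <- function(features, labels, config = winnow_config()) {
  features <- as.matrix(features)
  storage.mode(features) <- "integer"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("feature rows and label length must agree")
  if (nrow(features) == 0) stop("need at least one sample")
  theta <- config$threshold_fraction * ncol(features)
  w <- .winnow_train_cpp(features, labels, config$alpha, theta, config$epochs)
  names(w) <- colnames(features)
  w
}

#' Score directed gene-pair exclusivity with complementary Winnow runs
#'
#' For each classifier gene g two runs are trained against all other genes:
#' run 1 uses the complemented mutation matrix as features with g's status as
#' the label (an aberration in g should predict non-aberration elsewhere);
#' run 2 uses the original features with the complement of g's status as the
#' label. The directed weight `w(g -> j)` is the mean of the two runs'
#' weights for gene j. Deterministic given matrix and config.
#'
#' @param x mutation matrix with at least 2 genes.
#' @param config a [winnow_config()].
#' @return square matrix of directed weights (classifier gene in rows,
#'   `NA` on the diagonal).
#' @export
score_edges <- function(x, config = winnow_config()) {
  x <- as_mutation_matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need at least 2 genes to score edges")
  genes <- colnames(x)
  W <- matrix(NA_real_, p, p, dimnames = list(genes, genes))
  xc <- 1L - x
  for (g in seq_len(p)) {
    w1 <- winnow_fit(xc[, -g, drop = FALSE], x[, g], config)
    w2 <- winnow_fit(x[, -g, drop = FALSE], xc[, g], config)
    W[g, -g] <- (w1 + w2) / 2
  }
  W
}

#' Prune directed Winnow weights to a sparse exclusivity graph
#'
#' Because the weight scale of each classifier's run depends on how quickly
#' Winnow converges, no absolute cutoff is used: for each classifier gene the
#' outgoing edges with weight greater than or equal to its second-highest
#' outgoing weight are retained (ties included). An undirected edge survives
#' if retained from either side; its weight is the maximum retained directed
#' weight.
#'
#' @param weights directed weight matrix from [score_edges()].
#' @return an [igraph::igraph] with all genes as vertices, edge attribute
#'   `weight`, and the directed weight matrix stored as graph attribute
#'   `directed_weights`.
#' @export
prune_to_graph <- function(weights) {
  genes <- rownames(weights)
  if (is.null(genes) || !identical(genes, colnames(weights)))
    stop("weights must be a square named matrix")
  from <- character(0); to <- character(0); w <- numeric(0)
  for (g in seq_along(genes)) {
    out <- weights[g, -g]
    if (length(out) < 2) {
      keep <- names(out)
    } else {
      thr <- sort(out, decreasing = TRUE)[2]
      keep <- names(out)[out >= thr]
    }
    from <- c(from, rep(genes[g], length(keep)))
    to <- c(to, keep)
    w <- c(w, weights[g, keep])
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(w, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, character(1), 1),
                      to = vapply(parts, `[`, character(1), 2),
                      weight = as.numeric(agg), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  g <- igraph::set_graph_attr(g, "directed_weights", weights)
  g
}

#' Export an exclusivity graph as a tab-separated edge list
#'
#' @param graph igraph from [prune_to_graph()].
#' @param path file path; columns `gene_a`, `gene_b`, `weight`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
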