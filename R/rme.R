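#' Discover recurrent, mutually exclusive aberration modules
#'
#' Front end to the discovery pipeline ([run_discovery()]): from a binary
#' samples-by-genes aberration matrix it reports gene modules that are
#' recurrently altered across samples but almost never altered twice within
#' the same sample — the signature of genes whose disruption is functionally
#' interchangeable along a pathway. Module significance is established by the
#' algorithmic significance test ([d_score()]): a module is reported when a
#' pattern-aware encoder compresses its submatrix by at least `d_threshold`
#' bits relative to the independent-background null, after description
#' penalties that include an implicit multiple-testing correction.
#'
#' @param x mutation matrix (see [as_mutation_matrix()], [read_mutation_matrix()]).
#' @param min_recurrence,max_size,d_threshold see [discovery_config()].
#' @param n_total gene universe size before recurrence filtering; leave `NULL`
#'   when `x` is the unfiltered matrix.
#' @param winnow a [winnow_config()].
#' @param significance a [significance_config()].
#' @return object of class `rme` with the selected modules (`$modules`),
#'   the pruned exclusivity graph (`$graph`), the configuration, and
#'   bookkeeping counts. `summary()` yields a per-module data frame.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(k = 145, n = 1290, module_size = 3, coverage = 1,
#'                         seed = 11)
#' fit <- rme(sim$matrix)
#' fit
#' summary(fit)
#' setequal(fit$modules[[1]]$genes, sim$truth$genes)
#' }
#' @export
rme <- function(x, min_recurrence = 0.10, max_size = 5, d_threshold = 50,
                n_total = NULL, winnow = winnow_config(),
                significance = significance_config()) {
  cfg <- discovery_config(min_recurrence = min_recurrence,
                          max_module_size = max_size,
                          d_threshold = d_threshold,
                          winnow = winnow, significance = significance)
  res <- run_discovery(x, n_total = n_total, config = cfg)
  res$call <- match.call()
  res
}

module_table <- function(object) {
  mods <- object$modules
  if (length(mods) == 0)
    return(data.frame(rank = integer(0), genes = character(0),
                      size = integer(0), coverage = numeric(0),
                      exclusivity = numeric(0), d = numeric(0),
                      significance = numeric(0)))
  data.frame(
    rank = seq_along(mods),
    genes = vapply(mods, function(m) paste(m$genes, collapse = ","), character(1)),
    size = vapply(mods, function(m) length(m$genes), integer(1)),
    coverage = vapply(mods, `[[`, numeric(1), "coverage"),
    exclusivity = vapply(mods, `[[`, numeric(1), "exclusivity"),
    d = vapply(mods, `[[`, numeric(1), "d"),
    significance = vapply(mods, `[[`, numeric(1), "significance"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.rme <- function(x, ...) {
  cat("RME module discovery\n")
  cat(sprintf("  %d samples, %d genes after %.0f%% recurrence filter (universe %d)\n",
              x$k, x$n_filtered, 100 * x$config$min_recurrence, x$n_total))
  cat(sprintf("  %d connected candidate sets scored; d threshold %.0f bits\n",
              x$n_candidates, x$config$d_threshold))
  tab <- module_table(x)
  if (nrow(tab) == 0) {
    cat("  no modules above the significance threshold\n")
  } else {
    cat(sprintf("  %d disjoint module(s):\n", nrow(tab)))
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.rme <- function(object, ...) {
  tab <- module_table(object)
  structure(list(table = tab, k = object$k, n_filtered = object$n_filtered,
                 n_total = object$n_total, p_null = object$p_null,
                 config = object$config),
            class = "summary.rme")
}

#' @export
print.summary.rme <- function(x, ...) {
  cat(sprintf("Samples: %d   filtered genes: %d / %d   background p: %s\n",
              x$k, x$n_filtered, x$n_total,
              if (is.null(x$p_null)) "NA" else format(x$p_null, digits = 4)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot the pruned exclusivity graph with module membership
#'
#' @param x an `rme` fit.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.rme <- function(x, ...) {
  if (is.null(x$graph)) stop("no graph to plot (empty discovery result)")
  g <- x$graph
  memb <- rep(0L, igraph::vcount(g))
  names(memb) <- igraph::V(g)$name
  for (i in seq_along(x$modules)) memb[x$modules[[i]]$genes] <- i
  cols <- c("grey85", grDevices::hcl.colors(max(1, length(x$modules)), "Dark 3"))
  igraph::plot.igraph(
    g, vertex.color = cols[memb + 1L],
    edge.width = 1 + 3 * igraph::E(g)$weight / max(igraph::E(g)$weight),
    ...)
  invisible(x)
}
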