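#' Fit differential network-centrality gene rankings
#'
#' The main entry point: builds the per-instance normal/tumor induced
#' subgraph pairs and computes the selected per-gene measures over the node
#' universe.  Available measures:
#'
#' * `"bw"`, `"cc"`, `"deg1"`, `"deg2"` — differential sums of normalized
#'   betweenness, local clustering coefficient, first- and second-order
#'   degree (descending: large change ranks first);
#' * `"rw"`, `"gt"` — summed Pearson correlations of random-walk /
#'   shortest-path proximity columns (ascending: low similarity ranks
#'   first);
#' * `"j1"`, `"j2"` — summed neighborhood Jaccard indices (ascending);
#' * `"ed"`, `"mf"` — expression-difference and mutation-frequency
#'   controls (descending).
#'
#' @param network master interactome (undirected simple igraph with named
#'   vertices), or an `instance_set` already built with
#'   [build_instance_set()] (then `instances` is ignored).
#' @param instances list of [sample_instance()] objects.
#' @param measures character vector of measure names to compute.
#' @param walk a [walk_config()] for the random-walk measure.
#' @param indexing column-indexing mode for the proximity measures, see
#'   [column_correlation_measure()].
#' @return an object of class `diffcent`: list with `results` (named list
#'   of [measure_result()]), `instance_set`, `measures` and `call`.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, C - D, B - D)
#' inst <- list(
#'   sample_instance("p1", c("A", "B", "C", "D"), c("A", "C", "D"), "B"),
#'   sample_instance("p2", c("A", "B", "C", "D"), c("A", "B", "C", "D")))
#' fit <- diffcent(g, inst, measures = c("bw", "deg1"))
#' coef(fit)
#' @export
diffcent <- function(network, instances = NULL,
                     measures = c("bw", "cc", "deg1", "deg2",
                                  "rw", "gt", "j1", "j2", "ed", "mf"),
                     walk = walk_config(),
                     indexing = c("pair_union", "universe", "shared")) {
  indexing <- match.arg(indexing)
  valid <- c("bw", "cc", "deg1", "deg2", "rw", "gt", "j1", "j2", "ed", "mf")
  bad <- setdiff(measures, valid)
  if (length(bad) > 0L) {
    stop(sprintf("unknown measure(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  }
  iset <- if (inherits(network, "instance_set")) network
          else build_instance_set(network, instances)
  insts <- if (inherits(network, "instance_set")) {
    NULL
  } else {
    instances
  }
  results <- list()
  for (m in measures) {
    results[[m]] <- switch(
      m,
      bw = differential_sum(iset, betweenness_scores, "bw"),
      cc = differential_sum(iset, clustering_scores, "cc"),
      deg1 = differential_sum(iset, degree_order1, "deg1"),
      deg2 = differential_sum(iset, degree_order2, "deg2"),
      rw = column_correlation_measure(iset, "random_walk", walk, indexing),
      gt = column_correlation_measure(iset, "distance", walk, indexing),
      j1 = jaccard_measure(iset, 1L),
      j2 = jaccard_measure(iset, 2L),
      ed = {
        if (is.null(insts)) stop("measure 'ed' needs the instance list, not a prebuilt instance_set")
        expression_difference(insts, iset$universe)
      },
      mf = {
        if (is.null(insts)) stop("measure 'mf' needs the instance list, not a prebuilt instance_set")
        mutation_frequency(insts, iset$universe)
      })
  }
  structure(list(results = results, instance_set = iset,
                 measures = measures, call = match.call()),
            class = "diffcent")
}

#' @export
print.diffcent <- function(x, ...) {
  cat("Differential network-centrality fit\n")
  cat(sprintf("  %d instance pairs, %d genes in the universe\n",
              x$instance_set$pair_count, length(x$instance_set$universe)))
  cat("  measures:", paste(x$measures, collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene weight matrix of a fit
#'
#' @param object a `diffcent` fit.
#' @param ... unused.
#' @return numeric matrix, genes (universe) x measures.
#' @export
coef.diffcent <- function(object, ...) {
  uni <- object$instance_set$universe
  sapply(object$results, function(r) r$weights[uni])
}

#' Summarize a differential-centrality fit
#'
#' @param object a `diffcent` fit.
#' @param top number of top-ranked genes to report per measure.
#' @param ... unused.
#' @return object of class `summary.diffcent` holding the top genes and
#'   weight ranges per measure.
#' @export
summary.diffcent <- function(object, top = 10L, ...) {
  tab <- lapply(object$results, function(r) {
    g <- utils::head(ranked_genes(r), top)
    data.frame(measure = r$name, rank = seq_along(g), gene = g,
               weight = unname(r$weights[g]))
  })
  structure(list(top = do.call(rbind, tab),
                 pair_count = object$instance_set$pair_count,
                 n_genes = length(object$instance_set$universe)),
            class = "summary.diffcent")
}

#' @export
print.summary.diffcent <- function(x, ...) {
  cat(sprintf("diffcent fit: %d pairs, %d genes\n", x$pair_count, x$n_genes))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Plot ranked weight profiles of a fit
#'
#' Draws, per measure, the weight against the rank position (log-scaled
#' ranks), giving a quick view of how sharply each measure separates its
#' head from the bulk.
#'
#' @param x a `diffcent` fit.
#' @param measures subset of measures to draw; default all fitted.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diffcent <- function(x, measures = x$measures, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(measures)))
  on.exit(graphics::par(old))
  for (m in measures) {
    r <- x$results[[m]]
    w <- r$weights[ranked_genes(r)]
    graphics::plot(seq_along(w), w, type = "l", log = "x",
                   xlab = "rank", ylab = "weight",
                   main = sprintf("M_%s (%s)", m, r$direction), ...)
  }
  invisible(x)
}
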