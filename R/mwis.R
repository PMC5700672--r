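#' GWMIN2 greedy maximum-weight independent set
#'
#' Greedy heuristic for the (NP-complete) maximum weight independent set
#' problem: repeatedly select the node u maximizing
#' W(u) / sum of W over u's closed neighborhood, add it to the output, and
#' delete u and its neighbors; ratios are recomputed on the residual graph
#' each round.  Ties are broken by larger weight, then lexicographic node
#' id.  Nodes whose closed-neighborhood weight sum is zero are excluded
#' from the argmax (they carry no evidence and must not block weighted
#' neighbors); after the main loop any such nodes that ended up isolated
#' are appended.  The output weight is guaranteed to be at least
#' [gwmin2_bound()].
#'
#' @param graph undirected simple igraph (the conflict graph).
#' @param weights named non-negative weights covering every node.
#' @return list with `independent_set` (character vector) and
#'   `total_weight`.
#' @export
gwmin2 <- function(graph, weights) {
  nm <- igraph::V(graph)$name
  stopifnot(all(nm %in% names(weights)))
  w <- weights[nm]
  if (any(w < 0)) stop("gwmin2 requires non-negative weights")
  adj <- lapply(igraph::adjacent_vertices(graph, nm), function(v) v$name)
  names(adj) <- nm
  active <- stats::setNames(rep(TRUE, length(nm)), nm)
  chosen <- character(0)
  repeat {
    cand <- names(active)[active]
    if (length(cand) == 0L) break
    denom <- vapply(cand, function(u) {
      nbr <- adj[[u]]
      w[[u]] + sum(w[nbr[active[nbr]]])
    }, numeric(1))
    ok <- denom > 0
    if (!any(ok)) break
    ratio <- w[cand] / denom
    ratio[!ok] <- -Inf
    # argmax ratio, tie -> larger weight, tie -> lexicographic id
    best <- cand[order(-ratio, -w[cand], cand, method = "radix")][1L]
    chosen <- c(chosen, best)
    drop <- c(best, adj[[best]])
    active[drop[active[drop]]] <- FALSE
  }
  # zero-evidence leftovers: keep only those with no active neighbors
  leftover <- names(active)[active]
  for (u in leftover) {
    nbr <- adj[[u]]
    if (!any(active[nbr])) {
      chosen <- c(chosen, u)
      active[[u]] <- FALSE
    }
  }
  list(independent_set = chosen, total_weight = sum(w[chosen]))
}

#' GWMIN2 lower bound on the achievable independent-set weight
#'
#' Returns the theoretical guarantee
#' sum over nodes u of W(u)^2 / (sum of W over u's closed neighborhood);
#' terms with zero denominator contribute 0.
#'
#' @inheritParams gwmin2
#' @return a single number.
#' @export
gwmin2_bound <- function(graph, weights) {
  nm <- igraph::V(graph)$name
  stopifnot(all(nm %in% names(weights)))
  w <- weights[nm]
  adj <- igraph::adjacent_vertices(graph, nm)
  terms <- vapply(seq_along(nm), function(i) {
    denom <- w[[nm[i]]] + sum(w[adj[[i]]$name])
    if (denom == 0) 0 else w[[nm[i]]]^2 / denom
  }, numeric(1))
  sum(terms)
}

#' Filter a ranked measure with the GWMIN2 independent set
#'
#' Counters guilt-by-association: a gene may be ranked high only because
#' its interactome neighbors changed.  The interactome is induced on the
#' measure's universe, nodes are weighted by the measure (ascending
#' measures are flipped to non-negative importance weights via
#' `max(w) - w`), GWMIN2 selects an independent set, and the top `top_n`
#' surviving genes are returned in measure order.  The report covers every
#' ranked gene down to the `top_n`-th survivor and annotates each
#' non-survivor with its selected neighbors from that report, plus optional
#' per-gene expression/mutation counts and gold-standard membership flags.
#'
#' @param measure a [measure_result()].
#' @param network the master interactome.
#' @param top_n number of surviving genes to return.
#' @param instances optional list of [sample_instance()] objects used to
#'   fill the N (normal-expressed), T (tumor-expressed) and M
#'   (tumor-mutated) sample-count columns.
#' @param gold optional named list of gold-standard gene vectors; one
#'   logical flag column is added per list.
#' @return object of class `mwis_filter`: list with `genes` (the top_n
#'   survivors), `report` (data frame), `independent_set`, `total_weight`
#'   and `bound`.
#' @export
mwis_filter <- function(measure, network, top_n = 50L,
                        instances = NULL, gold = NULL) {
  stopifnot(inherits(measure, "measure_result"), top_n >= 1)
  uni <- names(measure$weights)
  cg <- igraph::induced_subgraph(network, intersect(uni, igraph::V(network)$name))
  w <- measure$weights
  if (measure$direction == "ascending") w <- max(w) - w
  sel <- gwmin2(cg, w)
  ranking <- ranked_genes(measure)
  in_set <- ranking %in% sel$independent_set
  n_surv <- cumsum(in_set)
  cut <- if (max(n_surv) >= top_n) which(n_surv == top_n)[1L] else length(ranking)
  rep_genes <- ranking[seq_len(cut)]
  rep_in <- in_set[seq_len(cut)]
  survivors_in_report <- rep_genes[rep_in]
  neigh <- vapply(seq_along(rep_genes), function(i) {
    if (rep_in[i]) return("")
    g <- rep_genes[i]
    if (!g %in% igraph::V(cg)$name) return("")
    nb <- igraph::neighbors(cg, g)$name
    paste(intersect(survivors_in_report, nb), collapse = ",")
  }, character(1))
  report <- data.frame(rank = seq_along(rep_genes),
                       gene = rep_genes,
                       weight = unname(measure$weights[rep_genes]),
                       in_mwis = rep_in,
                       mwis_neighbors = neigh,
                       stringsAsFactors = FALSE)
  if (!is.null(instances)) {
    report$N <- vapply(report$gene, function(g) {
      sum(vapply(instances, function(i) g %in% i$normal_expressed, logical(1)))
    }, numeric(1))
    report$T <- vapply(report$gene, function(g) {
      sum(vapply(instances, function(i) g %in% i$tumor_expressed, logical(1)))
    }, numeric(1))
    report$M <- vapply(report$gene, function(g) {
      sum(vapply(instances, function(i) g %in% i$tumor_mutated, logical(1)))
    }, numeric(1))
  }
  if (!is.null(gold)) {
    for (nmg in names(gold)) {
      report[[nmg]] <- report$gene %in% gold[[nmg]]
    }
  }
  structure(list(genes = survivors_in_report[seq_len(min(top_n, length(survivors_in_report)))],
                 report = report,
                 independent_set = sel$independent_set,
                 total_weight = sel$total_weight,
                 bound = gwmin2_bound(cg, w)),
            class = "mwis_filter")
}

#' @export
print.mwis_filter <- function(x, ...) {
  cat(sprintf("GWMIN2 filter: %d genes selected (total weight %.4g >= bound %.4g)\n",
              length(x$independent_set), x$total_weight, x$bound))
  cat(sprintf("  top survivors: %s\n",
              paste(utils::head(x$genes, 10L), collapse = ", ")))
  invisible(x)
}
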