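#' Normalized betweenness centrality
#'
#' Betweenness of a node is the sum over all unordered node pairs (s, t),
#' s != v != t, of the fraction of shortest s-t paths passing through v,
#' scaled by 2 / ((|V| - 1)(|V| - 2)) so values lie in \[0, 1\].
#' Disconnected pairs (no s-t path) contribute nothing.  Graphs with fewer
#' than three nodes score 0 everywhere (the normalization is undefined).
#'
#' @param graph undirected simple igraph.
#' @return named numeric vector over the graph's nodes.
#' @export
betweenness_scores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  nm <- igraph::V(graph)$name
  if (n < 3L) return(stats::setNames(numeric(n), nm))
  raw <- igraph::betweenness(graph, directed = FALSE, weights = NULL)
  stats::setNames(as.numeric(raw) * 2 / ((n - 1) * (n - 2)), nm)
}

#' Local clustering coefficient
#'
#' For a node v with degree d >= 2, twice the number of edges among v's
#' neighbors divided by d(d - 1); nodes with degree <= 1 score 0.
#'
#' @param graph undirected simple igraph.
#' @return named numeric vector over the graph's nodes.
#' @export
clustering_scores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  stats::setNames(as.numeric(cc), igraph::V(graph)$name)
}

#' First-order degree: size of the open neighborhood
#'
#' @param graph undirected simple igraph.
#' @return named integer-valued numeric vector.
#' @export
degree_order1 <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(igraph::degree(graph)), igraph::V(graph)$name)
}

#' Second-order degree: size of the two-step neighborhood
#'
#' Counts the union of a node's neighbors and all their neighbors.  Under
#' the literal reading a node with degree >= 1 is itself a neighbor of its
#' neighbors and so is counted; `include_self = FALSE` switches to the
#' variant that excludes the node.  Isolated nodes score 0 either way.
#'
#' @param graph undirected simple igraph.
#' @param include_self include the node itself whenever its degree is >= 1.
#' @return named numeric vector.
#' @export
degree_order2 <- function(graph, include_self = TRUE) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  deg <- igraph::degree(graph)
  ego <- igraph::ego_size(graph, order = 2)   # includes the node itself
  out <- ifelse(deg == 0L, 0, if (include_self) ego else ego - 1)
  stats::setNames(as.numeric(out), igraph::V(graph)$name)
}

#' Differential sum of a per-graph node score over all instance pairs
#'
#' The core aggregation of the unlabeled measures: for every gene v in the
#' universe, W(v) = sum over instances i of |score_{N_i}(v) - score_{T_i}(v)|,
#' where a gene absent from a graph scores 0 there.  Large weights flag
#' genes whose local/global topology changes most between normal and tumor
#' networks; the resulting measure ranks descending.
#'
#' @param instance_set an [build_instance_set()] result.
#' @param score_fn function(graph) -> named numeric scores.
#' @param name measure name for the result.
#' @return a [measure_result()] with descending direction.
#' @export
differential_sum <- function(instance_set, score_fn, name = "diff") {
  stopifnot(inherits(instance_set, "instance_set"))
  uni <- instance_set$universe
  w <- stats::setNames(numeric(length(uni)), uni)
  for (p in instance_set$pairs) {
    sn <- score_fn(p$normal)
    st <- score_fn(p$tumor)
    dn <- stats::setNames(numeric(length(uni)), uni)
    dn[names(sn)] <- sn
    dt <- stats::setNames(numeric(length(uni)), uni)
    dt[names(st)] <- st
    w <- w + abs(dn - dt)
  }
  measure_result(name, w, "descending")
}

#' Expression-difference control measure
#'
#' ED(v) is the absolute difference between the number of instances whose
#' normal sample expresses v and the number whose tumor sample expresses v.
#' Mutation status is ignored: a mutated-but-expressed tumor gene still
#' counts as expressed.
#'
#' @param instances list of [sample_instance()] objects.
#' @param universe genes over which the measure is defined (default: all
#'   genes seen in any expressed set).
#' @return a descending [measure_result()] named `"ed"`.
#' @export
expression_difference <- function(instances, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(instances, function(i) {
      c(i$normal_expressed, i$tumor_expressed)
    }))))
  }
  cn <- stats::setNames(numeric(length(universe)), universe)
  ct <- cn
  for (i in instances) {
    hitn <- intersect(i$normal_expressed, universe)
    hitt <- intersect(i$tumor_expressed, universe)
    cn[hitn] <- cn[hitn] + 1
    ct[hitt] <- ct[hitt] + 1
  }
  measure_result("ed", abs(cn - ct), "descending")
}

#' Mutation-frequency control measure
#'
#' MF(v) is the number of instances whose tumor sample carries a non-silent
#' mutation in v (instances, not records: repeated mutations within one
#' instance count once).
#'
#' @inheritParams expression_difference
#' @return a descending [measure_result()] named `"mf"`.
#' @export
mutation_frequency <- function(instances, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(instances, function(i) {
      c(i$normal_expressed, i$tumor_expressed, i$tumor_mutated)
    }))))
  }
  cm <- stats::setNames(numeric(length(universe)), universe)
  for (i in instances) {
    hit <- intersect(unique(i$tumor_mutated), universe)
    cm[hit] <- cm[hit] + 1
  }
  measure_result("mf", cm, "descending")
}
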