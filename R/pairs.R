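#' Build the normal/tumor graph pair for one patient instance
#'
#' The normal graph is the interactome induced on the genes expressed in the
#' patient's normal sample; the tumor graph is induced on the genes
#' expressed and not non-silently mutated in the tumor sample.  Genes absent
#' from the interactome fall outside both graphs.
#'
#' @param network the master interactome (undirected simple igraph).
#' @param instance a [sample_instance()].
#' @return an object of class `graph_pair` with elements `instance_id`,
#'   `normal` and `tumor` (both node-induced subgraphs of `network`).
#' @export
build_pair <- function(network, instance) {
  stopifnot(inherits(instance, "sample_instance"))
  vn <- igraph::V(network)$name
  normal_nodes <- intersect(instance$normal_expressed, vn)
  tumor_nodes <- intersect(setdiff(instance$tumor_expressed, instance$tumor_mutated), vn)
  structure(
    list(instance_id = instance$id,
         normal = igraph::induced_subgraph(network, normal_nodes),
         tumor = igraph::induced_subgraph(network, tumor_nodes)),
    class = "graph_pair")
}

#' Build the full instance set of graph pairs
#'
#' Constructs one [build_pair()] per instance (in input order) and the node
#' universe, the union of all normal and tumor node sets, over which every
#' measure is defined.  Genes present in the expression/mutation data but
#' absent from the interactome are excluded from the universe and reported
#' in `dropped_genes` for coverage auditing.
#'
#' @param network the master interactome.
#' @param instances non-empty list of [sample_instance()] objects.
#' @return an object of class `instance_set` with elements `pairs`,
#'   `universe`, `pair_count`, `network` and `dropped_genes`.
#' @export
build_instance_set <- function(network, instances) {
  if (length(instances) == 0L) stop("need at least one instance")
  pairs <- lapply(instances, build_pair, network = network)
  universe <- sort(unique(unlist(lapply(pairs, function(p) {
    c(igraph::V(p$normal)$name, igraph::V(p$tumor)$name)
  }))))
  seen <- unique(unlist(lapply(instances, function(i) {
    c(i$normal_expressed, i$tumor_expressed)
  })))
  structure(
    list(pairs = pairs,
         universe = universe,
         pair_count = length(pairs),
         network = network,
         dropped_genes = sort(setdiff(seen, igraph::V(network)$name))),
    class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("Instance set: %d normal/tumor graph pairs over %d genes\n",
              x$pair_count, length(x$universe)))
  if (length(x$dropped_genes) > 0L) {
    cat(sprintf("  (%d gene(s) outside the interactome were dropped)\n",
                length(x$dropped_genes)))
  }
  invisible(x)
}
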