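#' Random-walk configuration
#'
#' Parameters of the epsilon-biased lazy random walk used to build
#' proximity matrices.  At every step each node spreads its probability
#' mass equally over its closed neighborhood; a small constant `epsilon` is
#' subtracted from each contribution (negative contributions are clamped to
#' zero), which keeps the walker near its origin; the vector is then
#' renormalized.  Iteration stops when the L1 difference between successive
#' iterates drops to `convergence` or after `max_iterations` steps.
#'
#' @param epsilon non-negative bias constant, default `1e-4`.
#' @param convergence positive L1 stopping threshold, default `1e-6`.
#' @param max_iterations positive iteration cap, default 1000.
#' @return object of class `walk_config`.
#' @export
walk_config <- function(epsilon = 1e-4, convergence = 1e-6, max_iterations = 1000L) {
  stopifnot(epsilon >= 0, convergence > 0, max_iterations >= 1)
  structure(list(epsilon = epsilon, convergence = convergence,
                 max_iterations = as.integer(max_iterations)),
            class = "walk_config")
}

#' One row of the random-walk proximity matrix
#'
#' Runs the epsilon-biased walk from a single origin and returns the final
#' probability vector over the graph's nodes.
#'
#' @param graph undirected simple igraph.
#' @param origin origin node name (must be in the graph).
#' @param config a [walk_config()].
#' @return named probability vector (sums to 1).
#' @export
random_walk_row <- function(graph, origin, config = walk_config()) {
  nm <- igraph::V(graph)$name
  stopifnot(origin %in% nm)
  start <- stats::setNames(numeric(length(nm)), nm)
  start[origin] <- 1
  P <- walk_iterate(graph, matrix(start, nrow = 1, dimnames = list(origin, nm)),
                    config)
  stats::setNames(P[1L, ], nm)
}

#' Full random-walk proximity matrix
#'
#' Entry \[u, v\] is the converged probability that a walker started at u
#' sits at v.  Rows are origins and each row sums to 1.
#'
#' @inheritParams random_walk_row
#' @return numeric matrix with node names on both dimensions.
#' @export
random_walk_matrix <- function(graph, config = walk_config()) {
  nm <- igraph::V(graph)$name
  n <- length(nm)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  P0 <- diag(1, n)
  dimnames(P0) <- list(nm, nm)
  walk_iterate(graph, P0, config)
}

# Shared iteration: rows of P are walk distributions, updated as
# new[v] = sum_{s in Ne+(v)} max(0, old[s]/(deg(s)+1) - eps), renormalized.
walk_iterate <- function(graph, P, config) {
  nm <- igraph::V(graph)$name
  n <- length(nm)
  if (n == 1L) return(P)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  diag(A) <- 1                                # closed neighborhood
  deg1 <- igraph::degree(graph) + 1
  for (it in seq_len(config$max_iterations)) {
    C <- sweep(P, 2L, deg1, "/") - config$epsilon
    C[C < 0] <- 0
    newP <- C %*% A
    rs <- rowSums(newP)
    if (any(rs == 0)) {
      stop(sprintf("random walk collapsed to zero: epsilon = %g is too large",
                   config$epsilon))
    }
    newP <- newP / rs
    delta <- max(rowSums(abs(newP - P)))
    P <- newP
    if (delta <= config$convergence) break
  }
  P
}

#' Shortest-path distance matrix
#'
#' Entry \[u, v\] is the unweighted shortest-path length; the diagonal is 0.
#' Pairs in different components take the sentinel: 0 by default (mirroring
#' the convention that entries for absent nodes are 0), or `|V|` with
#' `sentinel = "nv"` — one more than any attainable path length, for users
#' who need "self" and "unreachable" kept distinct.
#'
#' @param graph undirected simple igraph.
#' @param sentinel `"zero"` or `"nv"` for unreachable pairs.
#' @return numeric matrix with node names on both dimensions.
#' @export
distance_matrix <- function(graph, sentinel = c("zero", "nv")) {
  sentinel <- match.arg(sentinel)
  n <- igraph::vcount(graph)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  D <- igraph::distances(graph)
  D[is.infinite(D)] <- if (sentinel == "zero") 0 else n
  D
}

#' Pearson correlation with a defined fallback
#'
#' Standard Pearson correlation of two equal-length vectors; if either
#' vector is constant (zero variance) the correlation is undefined and 0 is
#' returned, treating degenerate columns as uninformative.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("pcc: vectors must have equal length")
  if (length(x) < 2L) stop("pcc: vectors must have length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Column-wise Pearson correlations of two conformable matrices, with the
# constant-column fallback of pcc(); returns one value per column.
pcc_columns <- function(X, Y) {
  cx <- sweep(X, 2L, colMeans(X))
  cy <- sweep(Y, 2L, colMeans(Y))
  sx <- sqrt(colSums(cx^2))
  sy <- sqrt(colSums(cy^2))
  num <- colSums(cx * cy)
  out <- numeric(ncol(X))
  ok <- sx > 0 & sy > 0
  out[ok] <- num[ok] / (sx[ok] * sy[ok])
  out
}

#' Proximity-column correlation measures
#'
#' For each gene v and each instance pair, the v-columns of the normal and
#' tumor proximity matrices (random-walk probabilities or shortest-path
#' distances) are compared with the Pearson correlation; the measure weight
#' is the sum of these correlations over all instances, ranked ascending:
#' a low sum means v's network context changed.  Columns are re-indexed
#' over a common node set with zeros for absent entries; by default the
#' per-pair union of the two node sets is used (`indexing = "pair_union"`),
#' with the global universe or the per-pair intersection available as
#' alternatives.  A gene absent from both graphs of a pair contributes the
#' degenerate-correlation fallback 0.
#'
#' @param instance_set an [build_instance_set()] result.
#' @param kind `"random_walk"` or `"distance"`.
#' @param config a [walk_config()] (used by the random-walk kind).
#' @param indexing `"pair_union"`, `"universe"` or `"shared"`.
#' @param name measure name; defaults to `"rw"` or `"gt"`.
#' @return an ascending [measure_result()].
#' @export
column_correlation_measure <- function(instance_set,
                                       kind = c("random_walk", "distance"),
                                       config = walk_config(),
                                       indexing = c("pair_union", "universe", "shared"),
                                       name = NULL) {
  kind <- match.arg(kind)
  indexing <- match.arg(indexing)
  if (is.null(name)) name <- if (kind == "random_walk") "rw" else "gt"
  uni <- instance_set$universe
  w <- stats::setNames(numeric(length(uni)), uni)
  for (p in instance_set$pairs) {
    Mn <- if (kind == "random_walk") random_walk_matrix(p$normal, config)
          else distance_matrix(p$normal)
    Mt <- if (kind == "random_walk") random_walk_matrix(p$tumor, config)
          else distance_matrix(p$tumor)
    nn <- rownames(Mn) %||% character(0)
    nt <- rownames(Mt) %||% character(0)
    idx <- switch(indexing,
                  pair_union = sort(union(nn, nt)),
                  universe = uni,
                  shared = sort(intersect(nn, nt)))
    if (length(idx) < 2L) next
    Xn <- matrix(0, length(idx), length(uni), dimnames = list(idx, uni))
    Xt <- Xn
    if (length(nn) > 0L) {
      ri <- intersect(idx, nn)
      Xn[ri, nn] <- Mn[ri, , drop = FALSE]
    }
    if (length(nt) > 0L) {
      ri <- intersect(idx, nt)
      Xt[ri, nt] <- Mt[ri, , drop = FALSE]
    }
    w <- w + pcc_columns(Xn, Xt)
  }
  measure_result(name, w, "ascending")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Named list of neighborhood sets for every universe gene in a graph.
# order 1: open neighborhood Ne(v); order 2: Ne(v) plus all neighbors of
# Ne(v) (which re-includes v whenever deg(v) >= 1).  Genes absent from the
# graph, and isolated nodes, get the empty set.
neighborhood_sets <- function(graph, genes, order = 1L) {
  nm <- igraph::V(graph)$name
  out <- stats::setNames(vector("list", length(genes)), genes)
  present <- intersect(genes, nm)
  if (length(present) > 0L) {
    deg <- igraph::degree(graph, present)
    if (order == 1L) {
      nb <- igraph::adjacent_vertices(graph, present)
      for (i in seq_along(present)) out[[present[i]]] <- nb[[i]]$name
    } else {
      eg <- igraph::ego(graph, order = 2, nodes = present)
      for (i in seq_along(present)) {
        out[[present[i]]] <- if (deg[i] == 0L) character(0) else eg[[i]]$name
      }
    }
  }
  for (g in genes) if (is.null(out[[g]])) out[[g]] <- character(0)
  out
}

#' Neighborhood Jaccard measures
#'
#' For each gene and each instance pair, the Jaccard index of the gene's
#' neighborhoods in the normal and tumor graphs (first-order open
#' neighborhood, or the second-order neighborhood of [degree_order2()]);
#' the weight sums these indices over instances and ranks ascending.  When
#' both neighborhoods are empty the index is defined as 1 (nothing
#' changed).
#'
#' @param instance_set an [build_instance_set()] result.
#' @param order 1 or 2.
#' @param name measure name; defaults to `"j1"`/`"j2"`.
#' @return an ascending [measure_result()].
#' @export
jaccard_measure <- function(instance_set, order = 1L, name = NULL) {
  stopifnot(order %in% c(1L, 2L))
  if (is.null(name)) name <- paste0("j", order)
  uni <- instance_set$universe
  w <- stats::setNames(numeric(length(uni)), uni)
  for (p in instance_set$pairs) {
    sn <- neighborhood_sets(p$normal, uni, order)
    st <- neighborhood_sets(p$tumor, uni, order)
    for (g in uni) {
      a <- sn[[g]]
      b <- st[[g]]
      u <- length(union(a, b))
      w[[g]] <- w[[g]] + if (u == 0L) 1 else length(intersect(a, b)) / u
    }
  }
  measure_result(name, w, "ascending")
}
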