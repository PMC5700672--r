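# Independent brute-force oracles used across the suite.  They deliberately
# avoid the code paths (and graph-library algorithms) they are checking:
# everything here works on plain adjacency structures in base R.

# adjacency list (named list of character vectors) from an igraph
adj_list <- function(g) {
  nm <- igraph::V(g)$name
  out <- stats::setNames(lapply(igraph::adjacent_vertices(g, nm),
                                function(v) v$name), nm)
  out
}

# Enumerate all simple paths s -> t with DFS; keep the shortest ones.
# Returns list(count = number of shortest paths, through = named count of
# interior visits per node).
enumerate_shortest_paths <- function(adj, s, t) {
  nodes <- names(adj)
  best_len <- Inf
  best_paths <- list()
  stack <- list(list(path = s))
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    last <- cur$path[length(cur$path)]
    if (length(cur$path) - 1L > best_len) next
    if (last == t) {
      len <- length(cur$path) - 1L
      if (len < best_len) {
        best_len <- len
        best_paths <- list(cur$path)
      } else if (len == best_len) {
        best_paths <- c(best_paths, list(cur$path))
      }
      next
    }
    for (nb in adj[[last]]) {
      if (!(nb %in% cur$path)) {
        stack[[length(stack) + 1L]] <- list(path = c(cur$path, nb))
      }
    }
  }
  through <- stats::setNames(numeric(length(nodes)), nodes)
  for (p in best_paths) {
    interior <- setdiff(p, c(s, t))
    through[interior] <- through[interior] + 1
  }
  list(count = length(best_paths), through = through)
}

# Brute-force normalized betweenness over unordered pairs.
oracle_betweenness <- function(g) {
  adj <- adj_list(g)
  nodes <- names(adj)
  n <- length(nodes)
  bw <- stats::setNames(numeric(n), nodes)
  if (n < 3L) return(bw)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sp <- enumerate_shortest_paths(adj, nodes[i], nodes[j])
      if (sp$count > 0L) bw <- bw + sp$through / sp$count
    }
  }
  bw * 2 / ((n - 1) * (n - 2))
}

# Hand-rolled BFS all-pairs shortest-path lengths; unreachable -> Inf.
oracle_distances <- function(g) {
  adj <- adj_list(g)
  nodes <- names(adj)
  D <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[1L]
      queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Exhaustive maximum-weight independent set via bitmask enumeration (n <= 20).
oracle_mwis <- function(g, w) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  stopifnot(n <= 20L)
  adj <- adj_list(g)
  mask <- stats::setNames(integer(n), nodes)
  for (i in seq_len(n)) {
    for (nb in adj[[nodes[i]]]) {
      mask[i] <- bitwOr(mask[i], bitwShiftL(1L, match(nb, nodes) - 1L))
    }
  }
  subsets <- 0:(2^n - 1)
  ok <- rep(TRUE, length(subsets))
  weight <- rep(0, length(subsets))
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    inset <- bitwAnd(subsets, bit) > 0L
    ok <- ok & !(inset & bitwAnd(subsets, mask[i]) > 0L)
    weight <- weight + ifelse(inset, w[[nodes[i]]], 0)
  }
  max(weight[ok])
}

# Confusion-matrix ROC/PR oracle at arbitrary prefix sizes.
oracle_confusion <- function(ranking, gold, universe, size) {
  pred <- ranking[seq_len(size)]
  tp <- length(intersect(pred, gold))
  fp <- size - tp
  fn <- length(gold) - tp
  tn <- length(universe) - size - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn,
    tpr = tp / length(gold),
    fpr = if (length(universe) - length(gold) > 0) fp / (length(universe) - length(gold)) else 0,
    precision = tp / size, recall = tp / length(gold))
}

# Seeded Erdos-Renyi-style random named graph in base R + igraph container.
random_test_graph <- function(n, p = 0.4, connected = FALSE) {
  nodes <- paste0("n", seq_len(n))
  repeat {
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, n, name = nodes)
    if (any(keep)) g <- igraph::add_edges(g, pairs[, keep, drop = FALSE])
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

path_graph <- function(...) {
  nodes <- c(...)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(nodes) > 1L) {
    g <- igraph::add_edges(g, rbind(nodes[-length(nodes)], nodes[-1L]))
  }
  g
}

star_graph <- function(center, leaves) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, 1L + length(leaves), name = c(center, leaves))
  igraph::add_edges(g, rbind(center, leaves))
}

# tiny identity instance set: every N_i = T_i = the whole graph
identity_instances <- function(g, r = 3L) {
  genes <- igraph::V(g)$name
  lapply(seq_len(r), function(i) {
    sample_instance(paste0("id", i), genes, genes)
  })
}
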