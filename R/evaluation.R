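#' Head of a ranked list at a top-k percent cutoff
#'
#' Returns the first `ceiling(k/100 * length)` genes, so even `k = 1` on a
#' short list yields at least one gene.
#'
#' @param genes ranked character vector.
#' @param k percent in \[1, 100\].
#' @return character vector.
#' @export
top_fraction <- function(genes, k) {
  stopifnot(k >= 1, k <= 100)
  utils::head(genes, ceiling(k * length(genes) / 100))
}

#' Top-k percent ROC and precision/recall sweep
#'
#' Thresholds a ranked gene list at every integer percentile k = 1..100
#' (or at every rank with `resolution = "rank"`), computes the confusion
#' matrix against a gold-standard set over the given universe, and
#' integrates AUROC (over FPR/TPR, anchored at (0,0) and (1,1)) and AUPR
#' (over recall/precision) by the trapezoidal rule.  The gold standard is
#' intersected with the universe first.
#'
#' @param ranking ranked character vector (best first) covering the
#'   universe.
#' @param gold character vector of positive genes.
#' @param universe character vector of all evaluated genes; defaults to
#'   `ranking`.
#' @param resolution `"percent"` (the k = 1..100 sweep) or `"rank"` (one
#'   point per rank).
#' @return object of class `evaluation_curve`: list with `points` (data
#'   frame k, size, tp, fp, tpr, fpr, precision, recall), `auroc`, `aupr`.
#' @export
roc_pr_sweep <- function(ranking, gold, universe = ranking,
                         resolution = c("percent", "rank")) {
  resolution <- match.arg(resolution)
  ranking <- ranking[ranking %in% universe]
  gold <- intersect(gold, universe)
  if (length(gold) == 0L) stop("gold standard is empty after universe restriction")
  n <- length(universe)
  P <- length(gold)
  neg <- n - P
  pos <- ranking %in% gold
  cum_tp <- cumsum(pos)
  sizes <- if (resolution == "percent") {
    ceiling(seq_len(100) * length(ranking) / 100)
  } else {
    seq_along(ranking)
  }
  ks <- if (resolution == "percent") seq_len(100) else
    100 * sizes / length(ranking)
  tp <- cum_tp[sizes]
  fp <- sizes - tp
  tpr <- tp / P
  fpr <- if (neg > 0) fp / neg else rep(0, length(fp))
  precision <- tp / sizes
  recall <- tpr
  pts <- data.frame(k = ks, size = sizes, tp = tp, fp = fp,
                    tpr = tpr, fpr = fpr,
                    precision = precision, recall = recall)
  roc_x <- c(0, fpr, 1)
  roc_y <- c(0, tpr, 1)
  auroc <- trapezoid_area(roc_x, roc_y)
  pr_x <- c(0, recall)
  pr_y <- c(precision[1L], precision)
  aupr <- trapezoid_area(pr_x, pr_y)
  structure(list(points = pts, auroc = auroc, aupr = aupr,
                 resolution = resolution, n_gold = P, n_universe = n),
            class = "evaluation_curve")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.evaluation_curve <- function(x, ...) {
  cat(sprintf("Top-k%% sweep (%s resolution): AUROC %.3f, AUPR %.3f (%d gold / %d genes)\n",
              x$resolution, x$auroc, x$aupr, x$n_gold, x$n_universe))
  invisible(x)
}

#' @export
plot.evaluation_curve <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(c(0, x$points$fpr, 1), c(0, x$points$tpr, 1), type = "l",
                   xlab = "FPR", ylab = "TPR",
                   main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::plot(x$points$recall, x$points$precision, type = "l",
                   xlab = "recall", ylab = "precision",
                   main = sprintf("PR (AUPR %.3f)", x$aupr), ...)
  }
  invisible(x)
}

#' Restrict GO annotations to a fixed ontology level
#'
#' Standardizes annotation depth before computing consistency scores: a
#' term's level is its shortest directed distance to an ontology root.
#' Annotations above the target level (closer to the root) are dropped;
#' annotations below it are replaced by all their ancestors exactly at the
#' target level; annotations at the level are kept.
#'
#' @param annotation a [go_annotation()].
#' @param level target level, default 5.
#' @return a new [go_annotation()] on the same ontology.
#' @export
restrict_go_level <- function(annotation, level = 5L) {
  stopifnot(inherits(annotation, "go_annotation"), level >= 1)
  ont <- annotation$ontology
  levels <- go_term_levels(ont)
  terms <- names(levels)
  at_level <- terms[levels == level]
  # map: term -> its level-`level` representatives
  rep_map <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    if (levels[[t]] == level) {
      rep_map[[t]] <- t
    } else if (levels[[t]] > level) {
      anc <- igraph::subcomponent(ont, t, mode = "out")$name
      rep_map[[t]] <- intersect(anc, at_level)
    } else {
      rep_map[[t]] <- character(0)
    }
  }
  new_ann <- lapply(annotation$annotations, function(ts) {
    sort(unique(unlist(rep_map[ts])))
  })
  go_annotation(new_ann, ont)
}

#' GO consistency (GOC) score of a test list against a reference list
#'
#' GOC = (sum over all pairs (t in test, r in reference) of the Jaccard
#' index of their annotation sets) / |reference|.  Pairs whose annotation
#' union is empty contribute 0.  Annotations are expected to be
#' level-restricted already (see [restrict_go_level()]).
#'
#' @param test character vector of test genes (e.g. the top k% of a
#'   ranking).
#' @param reference non-empty character vector of reference genes.
#' @param annotation a [go_annotation()].
#' @return a single number; identical non-empty annotations everywhere
#'   give |test|.
#' @export
goc_score <- function(test, reference, annotation) {
  if (length(reference) == 0L) stop("reference gene list is empty")
  ann <- annotation$annotations
  get_ann <- function(g) if (g %in% names(ann)) ann[[g]] else character(0)
  total <- 0
  ref_sets <- lapply(reference, get_ann)
  for (t in test) {
    at <- get_ann(t)
    for (rs in ref_sets) {
      u <- length(union(at, rs))
      if (u > 0L) total <- total + length(intersect(at, rs)) / u
    }
  }
  total / length(reference)
}

#' GOC sweep over top-k percent prefixes
#'
#' @param ranking ranked character vector.
#' @param reference reference gene list.
#' @param annotation level-restricted [go_annotation()].
#' @param ks integer percents to evaluate, default 1..25.
#' @return data frame with columns `k` and `goc`.
#' @export
goc_sweep <- function(ranking, reference, annotation, ks = 1:25) {
  data.frame(k = ks,
             goc = vapply(ks, function(k) {
               goc_score(top_fraction(ranking, k), reference, annotation)
             }, numeric(1)))
}

#' Randomly rewire an interactome
#'
#' Simulates interaction noise: removes `round(ratio/100 * |E|)` edges
#' uniformly at random without replacement, then inserts the same number
#' of new edges between uniformly sampled node pairs that are non-adjacent
#' in the original network, rejecting self-loops, duplicates, and pairs
#' already adjacent in the evolving result.  The node set and the edge
#' count are preserved.
#'
#' @param network undirected simple igraph.
#' @param ratio percent of edges to rewire, in \[0, 100\].
#' @param seed optional integer seed making the rewiring reproducible.
#' @return the rewired igraph.
#' @export
rewire_network <- function(network, ratio, seed = NULL) {
  stopifnot(ratio >= 0, ratio <= 100)
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(network)
  n <- igraph::vcount(network)
  k <- round(ratio / 100 * m)
  if (k == 0L) return(network)
  if (n * (n - 1) / 2 - m < k) {
    stop("rewiring infeasible: not enough non-adjacent node pairs")
  }
  nm <- igraph::V(network)$name
  g <- igraph::delete_edges(network, sample.int(m, k))
  orig_el <- igraph::as_edgelist(network)
  taken <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(orig_el))) {
    assign(edge_key(orig_el[i, 1L], orig_el[i, 2L]), TRUE, envir = taken)
  }
  new_a <- character(k)
  new_b <- character(k)
  added <- 0L
  attempts <- 0L
  max_attempts <- 1000L * k + 10000L
  while (added < k) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("rewiring infeasible: rejection sampling exhausted")
    }
    pair <- nm[sample.int(n, 2L)]
    key <- edge_key(pair[1L], pair[2L])
    if (exists(key, envir = taken, inherits = FALSE)) next
    assign(key, TRUE, envir = taken)
    added <- added + 1L
    new_a[added] <- pair[1L]
    new_b[added] <- pair[2L]
  }
  igraph::add_edges(g, rbind(new_a, new_b))
}

edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "\r")

#' Rewiring configuration
#'
#' @param ratios rewiring percentages, default `c(5, 10, 15, 20)`.
#' @param replicates rewired networks per ratio, default 4.
#' @param seed base seed; replicate j at ratio index i uses
#'   `seed + 1000 * i + j`.
#' @return object of class `rewire_config`.
#' @export
rewire_config <- function(ratios = c(5, 10, 15, 20), replicates = 4L, seed = 1L) {
  stopifnot(all(ratios > 0), all(ratios <= 100), replicates >= 1)
  structure(list(ratios = ratios, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "rewire_config")
}

#' Rewiring robustness experiment
#'
#' For every rewiring ratio and replicate: rewire the interactome, rebuild
#' all normal/tumor pairs, recompute the requested measures, and evaluate
#' each against the gold standard with [roc_pr_sweep()].  Reports per
#' (measure, ratio) means and standard deviations across replicates,
#' prepended with the unrewired baseline (ratio 0), plus the number of
#' induced graphs constructed for the rewired networks
#' (2 * pair_count * |ratios| * replicates).
#'
#' @param network master interactome.
#' @param instances list of [sample_instance()] objects.
#' @param measures measure names understood by [diffcent()].
#' @param gold character vector of positive genes.
#' @param config a [rewire_config()].
#' @param walk a [walk_config()] for random-walk measures.
#' @return object of class `rewire_experiment`: list with `table` (data
#'   frame measure, ratio, mean_auroc, sd_auroc, mean_aupr, sd_aupr),
#'   `graphs_built` and `config`.
#' @export
rewiring_experiment <- function(network, instances, measures, gold,
                                config = rewire_config(),
                                walk = walk_config()) {
  eval_fit <- function(net) {
    fit <- diffcent(net, instances, measures = measures, walk = walk)
    lapply(fit$results, function(r) {
      cv <- roc_pr_sweep(ranked_genes(r), gold, fit$instance_set$universe)
      c(auroc = cv$auroc, aupr = cv$aupr)
    })
  }
  base <- eval_fit(network)
  rows <- list()
  for (m in measures) {
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, ratio = 0,
      mean_auroc = base[[m]][["auroc"]], sd_auroc = 0,
      mean_aupr = base[[m]][["aupr"]], sd_aupr = 0)
  }
  graphs_built <- 0L
  for (i in seq_along(config$ratios)) {
    r <- config$ratios[i]
    reps <- vector("list", config$replicates)
    for (j in seq_len(config$replicates)) {
      gw <- rewire_network(network, r, seed = config$seed + 1000L * i + j)
      reps[[j]] <- eval_fit(gw)
      graphs_built <- graphs_built + 2L * length(instances)
    }
    for (m in measures) {
      aurocs <- vapply(reps, function(x) x[[m]][["auroc"]], numeric(1))
      auprs <- vapply(reps, function(x) x[[m]][["aupr"]], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, ratio = r,
        mean_auroc = mean(aurocs), sd_auroc = stats::sd(aurocs),
        mean_aupr = mean(auprs), sd_aupr = stats::sd(auprs))
    }
  }
  message(sprintf("rewiring experiment built %d induced graphs (plus %d for the baseline)",
                  graphs_built, 2L * length(instances)))
  structure(list(table = do.call(rbind, rows),
                 graphs_built = graphs_built,
                 config = config),
            class = "rewire_experiment")
}

#' @export
print.rewire_experiment <- function(x, ...) {
  cat(sprintf("Rewiring experiment (%d rewired graphs built):\n", x$graphs_built))
  print(x$table, row.names = FALSE)
  invisible(x)
}
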