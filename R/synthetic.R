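#' Synthetic study configuration
#'
#' Defines the conditions of the bundled synthetic study: a scale-free
#' interactome, paired per-patient expressed-gene sets with planted driver
#' genes perturbed on the tumor side, sparse non-silent mutation calls, and
#' a toy ontology.  Drivers are the highest-degree genes; in each tumor
#' sample a driver perturbation (with probability `driver_dropout`) removes
#' either the driver itself or a random half of its neighbors from the
#' expressed set, degrading the driver's tumor-side centrality while
#' background genes only fluctuate via `background_flip`.
#'
#' @param n_genes number of genes, default 500.
#' @param attachment_degree edges each new node attaches with in the
#'   scale-free generator, default 2.
#' @param n_instances number of paired normal/tumor patients, default 40.
#' @param n_drivers number of planted drivers, default 15.
#' @param driver_dropout per-driver per-sample perturbation probability,
#'   default 0.6.
#' @param background_flip per-gene per-sample probability of dropping out
#'   of an expressed set, default 0.02.
#' @param mutation_rate per-gene per-tumor-sample non-silent mutation
#'   probability, default 0.01.
#' @param driver_removal `"mixed"` (coin flip between the two modes),
#'   `"driver"` (always remove the driver) or `"neighbors"` (always remove
#'   a sampled half of its neighbors).
#' @param seed integer seed; the same seed reproduces every artifact
#'   exactly.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L, attachment_degree = 2L,
                             n_instances = 40L, n_drivers = 15L,
                             driver_dropout = 0.6, background_flip = 0.02,
                             mutation_rate = 0.01,
                             driver_removal = c("mixed", "driver", "neighbors"),
                             seed = 7L) {
  driver_removal <- match.arg(driver_removal)
  stopifnot(n_genes >= attachment_degree + 1, n_drivers < n_genes,
            driver_dropout >= 0, driver_dropout <= 1,
            background_flip >= 0, background_flip <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 attachment_degree = as.integer(attachment_degree),
                 n_instances = as.integer(n_instances),
                 n_drivers = as.integer(n_drivers),
                 driver_dropout = driver_dropout,
                 background_flip = background_flip,
                 mutation_rate = mutation_rate,
                 driver_removal = driver_removal,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic scale-free interactome
#'
#' Preferential-attachment (Barabasi-Albert) graph: connected, simple,
#' heavy-tailed degree distribution, deterministic under the config seed.
#' Gene ids are `G0001`, `G0002`, ...
#'
#' @param config a [synthetic_config()].
#' @return undirected simple igraph.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- igraph::sample_pa(config$n_genes, m = config$attachment_degree,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(config$n_genes))
  g
}

#' Generate paired patient instances with planted drivers
#'
#' Drivers are the `n_drivers` highest-degree genes of the interactome
#' (ties broken lexicographically), guaranteeing non-trivial centrality.
#' Per instance: the normal expressed set is all genes minus independent
#' background flips; the tumor expressed set is all genes minus independent
#' background flips, minus driver perturbations (see [synthetic_config()]);
#' tumor mutations hit each gene independently at `mutation_rate`.
#'
#' @param config a [synthetic_config()].
#' @param network the interactome from [generate_network()].
#' @return list with `instances` (list of [sample_instance()]) and `gold`
#'   (the planted driver gene ids).
#' @export
generate_instances <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  genes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  drivers <- genes[order(-deg, genes, method = "radix")][seq_len(config$n_drivers)]
  nbrs <- lapply(igraph::adjacent_vertices(network, drivers), function(v) v$name)
  names(nbrs) <- drivers
  instances <- vector("list", config$n_instances)
  for (i in seq_len(config$n_instances)) {
    normal <- genes[stats::runif(length(genes)) >= config$background_flip]
    tumor <- genes[stats::runif(length(genes)) >= config$background_flip]
    for (d in drivers) {
      if (stats::runif(1) < config$driver_dropout) {
        mode <- switch(config$driver_removal,
                       mixed = if (stats::runif(1) < 0.5) "driver" else "neighbors",
                       config$driver_removal)
        if (mode == "driver") {
          tumor <- setdiff(tumor, d)
        } else {
          hit <- nbrs[[d]][stats::runif(length(nbrs[[d]])) < 0.5]
          tumor <- setdiff(tumor, hit)
        }
      }
    }
    mutated <- genes[stats::runif(length(genes)) < config$mutation_rate]
    instances[[i]] <- sample_instance(sprintf("P%03d", i), normal, tumor, mutated)
  }
  list(instances = instances, gold = drivers)
}

#' Generate a toy GO-style ontology and annotations
#'
#' Builds a DAG of depth 8 with a known level structure: a root, a spine of
#' generic terms at each level, a block of level-5 terms shared by the gold
#' (driver) genes, a disjoint pool of level-5 background terms, and a few
#' depth-7 descendants of the gold block (so level restriction has deeper
#' annotations to lift).  Gold genes draw most annotations from the gold
#' block; background genes draw from the background pool with a small
#' chance of touching the gold block.  Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param gold character vector of driver gene ids.
#' @param background character vector of the remaining gene ids.
#' @return a [go_annotation()].
#' @export
generate_go <- function(config, gold, background) {
  set.seed(config$seed + 2L)
  depth <- 8L
  spine <- sprintf("TERM:L%d", seq_len(depth))        # level i chain term
  root <- "TERM:ROOT"                                 # level 0
  gold_block <- sprintf("TERM:GOLD%02d", 1:6)         # level 5
  bg_pool <- sprintf("TERM:BG%02d", 1:30)             # level 5
  deep <- sprintf("TERM:DEEP%02d", 1:4)               # level 7, under gold block
  deep_mid <- sprintf("TERM:MID%02d", 1:4)            # level 6 links
  shallow <- sprintf("TERM:SHALLOW%02d", 1:3)         # level 3, dropped on restrict
  edges <- rbind(
    cbind(spine[1L], root),
    cbind(spine[-1L], spine[-depth]),
    cbind(gold_block, spine[4L]),
    cbind(bg_pool, spine[4L]),
    cbind(deep_mid, gold_block[1:4]),
    cbind(deep, deep_mid),
    cbind(shallow, spine[2L]))
  terms <- unique(c(root, spine, gold_block, bg_pool, deep, deep_mid, shallow))
  ont <- igraph::make_empty_graph(0, directed = TRUE)
  ont <- igraph::add_vertices(ont, length(terms), name = terms)
  ont <- igraph::add_edges(ont, t(edges))
  ann <- list()
  for (g in gold) {
    n_main <- 3L + stats::rbinom(1L, 2L, 0.5)
    picked <- sample(gold_block, min(n_main, length(gold_block)))
    if (stats::runif(1) < 0.5) picked <- c(picked, sample(deep, 1L))
    if (stats::runif(1) < 0.3) picked <- c(picked, sample(bg_pool, 1L))
    ann[[g]] <- unique(picked)
  }
  for (g in background) {
    picked <- sample(bg_pool, 2L + stats::rbinom(1L, 2L, 0.5))
    if (stats::runif(1) < 0.05) picked <- c(picked, sample(gold_block, 1L))
    if (stats::runif(1) < 0.2) picked <- c(picked, sample(shallow, 1L))
    ann[[g]] <- unique(picked)
  }
  go_annotation(ann, ont)
}

#' Write a full synthetic data set in the package's external formats
#'
#' Emits `network.tsv` (edge list), `expression.tsv` (RPKM table whose
#' >= 1 calls reproduce the generated expressed sets), `mutations.tsv`,
#' `gold.txt`, `toy.obo`, `toy.gaf` and `config.json` into a directory, so
#' the file-reading path of the pipeline is exercised end to end.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated `network`, `instances`,
#'   `gold`, `annotation` and the file paths.
#' @export
write_synthetic_data <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_network(config)
  gi <- generate_instances(config, network)
  genes <- igraph::V(network)$name
  ann <- generate_go(config, gi$gold, setdiff(genes, gi$gold))
  paths <- list(network = file.path(dir, "network.tsv"),
                expression = file.path(dir, "expression.tsv"),
                mutations = file.path(dir, "mutations.tsv"),
                gold = file.path(dir, "gold.txt"),
                obo = file.path(dir, "toy.obo"),
                gaf = file.path(dir, "toy.gaf"),
                config = file.path(dir, "config.json"))
  write_edge_list(network, paths$network)
  set.seed(config$seed + 3L)
  vals <- matrix(0, length(genes), 2L * config$n_instances)
  cn <- character(2L * config$n_instances)
  for (i in seq_along(gi$instances)) {
    inst <- gi$instances[[i]]
    cn[2L * i - 1L] <- paste0(inst$id, "_normal")
    cn[2L * i] <- paste0(inst$id, "_tumor")
    expr_n <- genes %in% inst$normal_expressed
    expr_t <- genes %in% inst$tumor_expressed
    vals[, 2L * i - 1L] <- ifelse(expr_n, 1 + stats::rexp(length(genes), 1 / 20),
                                  stats::runif(length(genes), 0, 0.99))
    vals[, 2L * i] <- ifelse(expr_t, 1 + stats::rexp(length(genes), 1 / 20),
                             stats::runif(length(genes), 0, 0.99))
  }
  df <- data.frame(gene = genes, vals, check.names = FALSE)
  names(df) <- c("gene", cn)
  utils::write.table(df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  recs <- do.call(rbind, lapply(gi$instances, function(inst) {
    if (length(inst$tumor_mutated) == 0L) return(NULL)
    data.frame(gene = inst$tumor_mutated, instance = inst$id,
               variant_classification = "Missense_Mutation")
  }))
  if (is.null(recs)) {
    recs <- data.frame(gene = character(0), instance = character(0),
                       variant_classification = character(0))
  }
  utils::write.table(recs, paths$mutations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("# planted driver genes", gi$gold), paths$gold)
  write_obo(ann$ontology, paths$obo)
  write_gaf(ann$annotations, paths$gaf)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE)
  invisible(list(network = network, instances = gi$instances,
                 gold = gi$gold, annotation = ann, paths = paths))
}

# Minimal OBO 1.2 writer for the toy ontology (is_a edges only).
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in igraph::V(ontology)$name) {
    parents <- igraph::neighbors(ontology, t, mode = "out")$name
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: ", t)), con)
    for (p in parents) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

# Minimal GAF 2.2 writer (17 columns, gene symbol in column 3).
write_gaf <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (g in names(annotations)) {
    for (t in annotations[[g]]) {
      row <- c("SYNTH", g, g, "", t, "SYNTH:1", "IEA", "", "P",
               "", "", "protein", "taxon:9606", "20260101", "SYNTH", "", "")
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}
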