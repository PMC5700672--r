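#' Pipeline stage: generate a synthetic data set
#'
#' Thin wrapper over [write_synthetic_data()] used by the `simulate` CLI
#' subcommand.
#'
#' @param out_dir output directory.
#' @param config a [synthetic_config()].
#' @return invisibly, the [write_synthetic_data()] result.
#' @export
run_simulate <- function(out_dir, config = synthetic_config()) {
  res <- write_synthetic_data(config, out_dir)
  message(sprintf("wrote synthetic data set (%d genes, %d instances) to %s",
                  config$n_genes, config$n_instances, out_dir))
  invisible(res)
}

#' Pipeline stage: score all selected measures from input files
#'
#' Reads the interactome, expression and mutation files, builds the
#' instance pairs, fits [diffcent()] and writes one ranked TSV per measure
#' plus a JSON manifest (configuration, input checksums, package version)
#' sufficient to reproduce the run.
#'
#' @param network_file edge-list TSV of the interactome.
#' @param expression_file RPKM TSV (see [read_expression()]).
#' @param mutation_file mutation TSV (see [read_mutations()]); optional.
#' @param out_dir output directory.
#' @param measures measure names, see [diffcent()].
#' @param threshold RPKM expression threshold, default 1.
#' @param silent_labels variant classifications treated as silent.
#' @param walk a [walk_config()].
#' @return invisibly, the fitted `diffcent` object.
#' @export
run_score <- function(network_file, expression_file, mutation_file = NULL,
                      out_dir = ".",
                      measures = c("bw", "cc", "deg1", "deg2",
                                   "rw", "gt", "j1", "j2", "ed", "mf"),
                      threshold = 1, silent_labels = "Silent",
                      walk = walk_config()) {
  for (f in c(network_file, expression_file, mutation_file)) {
    if (!is.null(f) && !file.exists(f)) stop(sprintf("input not found: %s", f))
  }
  network <- read_edge_list(network_file)
  expressed <- call_expressed(read_expression(expression_file), threshold)
  mutated <- if (is.null(mutation_file)) list()
             else call_mutated(read_mutations(mutation_file), silent_labels)
  instances <- make_instances(expressed, mutated)
  fit <- diffcent(network, instances, measures = measures, walk = walk)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in measures) {
    write_measure_tsv(fit$results[[m]], file.path(out_dir, paste0("M_", m, ".tsv")))
  }
  inputs <- c(network = network_file, expression = expression_file,
              mutations = mutation_file)
  manifest <- list(
    stage = "score",
    package_version = as.character(utils::packageVersion("diffcent")),
    measures = measures,
    threshold = threshold,
    silent_labels = silent_labels,
    walk = unclass(walk),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

#' Pipeline stage: GWMIN2 filtering report
#'
#' @param measure_file ranked TSV written by [run_score()].
#' @param network_file edge-list TSV of the interactome.
#' @param out_file output TSV path for the filter report.
#' @param top_n survivors to report, default 50.
#' @param direction sort direction of the measure in `measure_file`.
#' @param gold_files optional named character vector of gold-standard list
#'   files; adds one membership flag column each.
#' @return invisibly, the [mwis_filter()] result.
#' @export
run_mwis <- function(measure_file, network_file, out_file, top_n = 50L,
                     direction = c("descending", "ascending"),
                     gold_files = NULL) {
  direction <- match.arg(direction)
  measure <- read_measure_tsv(measure_file, direction = direction)
  network <- read_edge_list(network_file)
  gold <- if (is.null(gold_files)) NULL else lapply(gold_files, read_gene_list)
  res <- mwis_filter(measure, network, top_n = top_n, gold = gold)
  utils::write.table(res$report, out_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}

#' Pipeline stage: ROC/PR and GOC evaluation of ranked lists
#'
#' Evaluates every ranked measure TSV against each gold-standard list
#' (intersected with the ranking's universe) and writes a summary TSV
#' (rows: gold standard x metric; columns: measures) plus per-measure
#' curve TSVs; when an ontology and annotation file are given, also a GOC
#' sweep TSV over k = 1..25.
#'
#' @param measure_files named character vector of ranked TSVs (names are
#'   measure labels).
#' @param directions character vector of sort directions matching
#'   `measure_files`.
#' @param gold_files named character vector of gold-standard list files.
#' @param out_dir output directory.
#' @param obo_file,gaf_file optional ontology / annotation files enabling
#'   the GOC sweep.
#' @param go_level ontology restriction level, default 5.
#' @return invisibly, a list with the summary data frame and curves.
#' @export
run_evaluate <- function(measure_files, directions, gold_files, out_dir = ".",
                         obo_file = NULL, gaf_file = NULL, go_level = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  measures <- mapply(function(f, d) read_measure_tsv(f, direction = d),
                     measure_files, directions, SIMPLIFY = FALSE)
  golds <- lapply(gold_files, read_gene_list)
  summary_rows <- list()
  curves <- list()
  for (m in names(measures)) {
    ranking <- ranked_genes(measures[[m]])
    for (g in names(golds)) {
      gold <- intersect(golds[[g]], ranking)
      if (length(gold) == 0L) {
        stop(sprintf("gold list '%s' is empty after universe intersection", g))
      }
      cv <- roc_pr_sweep(ranking, gold, ranking)
      curves[[paste(m, g, sep = ".")]] <- cv
      utils::write.table(cv$points,
                         file.path(out_dir, sprintf("curve_%s_%s.tsv", m, g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        gold = g, measure = m, auroc = cv$auroc, aupr = cv$aupr)
    }
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(obo_file) && !is.null(gaf_file)) {
    ann <- restrict_go_level(read_gaf(gaf_file, read_obo(obo_file)), go_level)
    goc_rows <- list()
    for (m in names(measures)) {
      ranking <- ranked_genes(measures[[m]])
      for (g in names(golds)) {
        sw <- goc_sweep(ranking, intersect(golds[[g]], ranking), ann)
        sw$measure <- m
        sw$gold <- g
        goc_rows[[length(goc_rows) + 1L]] <- sw
      }
    }
    utils::write.table(do.call(rbind, goc_rows),
                       file.path(out_dir, "goc_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(summary = summary, curves = curves))
}

#' Pipeline stage: rewiring robustness experiment from input files
#'
#' @param network_file,expression_file,mutation_file input files as in
#'   [run_score()].
#' @param gold_file gold-standard gene list file.
#' @param out_file output TSV for the per-(measure, ratio) summary table.
#' @param measures measure names, default the two best performers.
#' @param config a [rewire_config()].
#' @param threshold RPKM expression threshold.
#' @return invisibly, the [rewiring_experiment()] result.
#' @export
run_rewire <- function(network_file, expression_file, mutation_file = NULL,
                       gold_file, out_file,
                       measures = c("bw", "deg1"),
                       config = rewire_config(), threshold = 1) {
  network <- read_edge_list(network_file)
  expressed <- call_expressed(read_expression(expression_file), threshold)
  mutated <- if (is.null(mutation_file)) list()
             else call_mutated(read_mutations(mutation_file))
  instances <- make_instances(expressed, mutated)
  gold <- read_gene_list(gold_file)
  res <- rewiring_experiment(network, instances, measures, gold, config)
  utils::write.table(res$table, out_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}
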