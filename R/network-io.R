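#' Read a protein-protein interaction network from a two-column edge list
#'
#' Builds a simple undirected interactome from a delimited text file with one
#' interacting gene pair per line.  Duplicate lines, reversed duplicates and
#' self-loops are collapsed or dropped, so the result is always a simple
#' graph; dropped self-loops and collapsed duplicates are reported via
#' [message()].
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter, default tab.
#' @param header logical; if `TRUE` the first line is skipped.
#' @return an undirected simple [igraph::igraph] with gene identifiers as
#'   vertex names.
#' @export
read_edge_list <- function(path, delimiter = "\t", header = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) >= 1L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_network())
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, function(p) sum(nzchar(trimws(p))) < 2L, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list line %d in '%s': expected two fields",
                 bad[1L] + as.integer(header), path))
  }
  a <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
  b <- vapply(parts, function(p) trimws(p[[2L]]), character(1))
  make_ppi_network(a, b)
}

empty_network <- function() {
  igraph::make_empty_graph(0, directed = FALSE)
}

#' Build a simple undirected network from endpoint vectors
#'
#' Internal constructor shared by all network readers: drops self-loops
#' (with a logged count) and collapses duplicate / reversed-duplicate edges.
#'
#' @param a,b character vectors of edge endpoints.
#' @param extra_nodes additional isolated node names to include.
#' @return an undirected simple igraph.
#' @keywords internal
make_ppi_network <- function(a, b, extra_nodes = character(0)) {
  loops <- a == b
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
  }
  nodes <- sort(unique(c(a, b, extra_nodes)))
  a2 <- a[!loops]
  b2 <- b[!loops]
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  }
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(lo[!dup]) > 0L) {
    g <- igraph::add_edges(g, rbind(lo[!dup], hi[!dup]))
  }
  g
}

#' Write a network as a two-column tab-separated edge list
#'
#' @param network an undirected igraph with named vertices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PSI-MITAB 2.5-style interaction file
#'
#' Keeps rows whose interaction type matches a physical-interaction
#' vocabulary and (when interactor-type columns are present, as in MITAB 2.6+)
#' whose both interactors are proteins.  Interactor identifiers are taken
#' from the unique-identifier columns; the value after the first `:` in the
#' first entry of each field is used (e.g. `uniprotkb:P04637` maps to
#' `P04637`).
#'
#' @param path path to the MITAB file.  Lines starting with `#` are skipped.
#' @param physical_pattern regular expression matched (case-insensitively)
#'   against the interaction-type field; rows that do not match are dropped.
#'   The default keeps MI terms whose names mention "physical" or
#'   "direct interaction".
#' @param protein_pattern regular expression a MITAB 2.6 interactor-type
#'   field must match for the interactor to count as a protein; ignored when
#'   the file has no interactor-type columns.
#' @return an undirected simple igraph.
#' @export
read_mitab <- function(path,
                       physical_pattern = "physical|direct interaction",
                       protein_pattern = "protein|MI:0326") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_network())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(rows))
  if (ncol_min < 12L) {
    stop("MITAB format error: expected at least 12 tab-separated columns")
  }
  id_a <- vapply(rows, function(r) mitab_primary_id(r[[1L]]), character(1))
  id_b <- vapply(rows, function(r) mitab_primary_id(r[[2L]]), character(1))
  itype <- vapply(rows, function(r) r[[12L]], character(1))
  keep <- grepl(physical_pattern, itype, ignore.case = TRUE)
  if (ncol_min >= 22L) {
    ta <- vapply(rows, function(r) r[[21L]], character(1))
    tb <- vapply(rows, function(r) r[[22L]], character(1))
    keep <- keep &
      grepl(protein_pattern, ta, ignore.case = TRUE) &
      grepl(protein_pattern, tb, ignore.case = TRUE)
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("dropped %d non-physical or non-protein row(s)", dropped))
  }
  if (!any(keep)) return(empty_network())
  make_ppi_network(id_a[keep], id_b[keep])
}

# "uniprotkb:P04637|intact:EBI-123" -> "P04637"
mitab_primary_id <- function(field) {
  first <- strsplit(field, "|", fixed = TRUE)[[1L]][1L]
  sub("^[^:]*:", "", first)
}

#' Read a gene x sample RPKM expression table
#'
#' The file is a TSV with genes as rows (first column holds the gene id) and
#' one column per sample named `<instance>_normal` or `<instance>_tumor`.
#'
#' @param path path to the TSV file.
#' @return an object of class `expression_table` with elements `genes`,
#'   `samples` (data frame with `instance` and `tissue`) and `values`
#'   (numeric matrix, genes x samples).
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  expression_table(genes, colnames(vals), vals)
}

expression_table <- function(genes, sample_names, values) {
  tissue <- sub("^.*_", "", sample_names)
  if (!all(tissue %in% c("normal", "tumor"))) {
    stop("expression sample columns must be named '<instance>_normal' or '<instance>_tumor'")
  }
  if (any(values < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  structure(
    list(genes = genes,
         samples = data.frame(instance = sub("_(normal|tumor)$", "", sample_names),
                              tissue = tissue, stringsAsFactors = FALSE),
         values = values),
    class = "expression_table")
}

#' Call expressed genes per sample from an RPKM table
#'
#' A gene is called expressed in a sample iff its RPKM value is greater than
#' or equal to `threshold` (the boundary value itself counts as expressed).
#'
#' @param table an `expression_table`.
#' @param threshold non-negative RPKM cutoff, default 1.
#' @return a named list: one element per instance, each a list with
#'   character vectors `normal` and `tumor` of expressed gene ids (missing
#'   tissues yield empty vectors).
#' @export
call_expressed <- function(table, threshold = 1) {
  stopifnot(inherits(table, "expression_table"), threshold >= 0)
  out <- list()
  for (j in seq_len(ncol(table$values))) {
    inst <- table$samples$instance[j]
    tis <- table$samples$tissue[j]
    expressed <- table$genes[!is.na(table$values[, j]) & table$values[, j] >= threshold]
    if (is.null(out[[inst]])) {
      out[[inst]] <- list(normal = character(0), tumor = character(0))
    }
    out[[inst]][[tis]] <- unique(c(out[[inst]][[tis]], expressed))
  }
  out
}

#' Read a mutation table
#'
#' Expects a TSV with columns `gene`, `instance` and `variant_classification`
#' (a MAF-style file is accepted by passing `col_map`, e.g.
#' `c(gene = "Hugo_Symbol", instance = "Tumor_Sample_Barcode",
#' variant_classification = "Variant_Classification")`).
#'
#' @param path path to the TSV file.
#' @param col_map optional named character vector mapping the canonical
#'   column names to the file's column names.
#' @return an object of class `mutation_table` wrapping the records.
#' @export
read_mutations <- function(path, col_map = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  wanted <- c("gene", "instance", "variant_classification")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        stop(sprintf("mutation file lacks mapped column '%s'", col_map[[canon]]))
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("mutation file lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  mutation_table(df[, wanted])
}

mutation_table <- function(records) {
  stopifnot(is.data.frame(records))
  structure(list(records = records), class = "mutation_table")
}

#' Call non-silently mutated genes per instance
#'
#' A gene counts as mutated in an instance iff it has at least one record
#' whose variant classification is not in `silent_labels`; multiple records
#' for the same gene and instance count once (set semantics).
#'
#' @param table a `mutation_table`.
#' @param silent_labels variant classifications to ignore, default
#'   `"Silent"`.
#' @return named list: instance id -> character vector of mutated gene ids.
#' @export
call_mutated <- function(table, silent_labels = "Silent") {
  stopifnot(inherits(table, "mutation_table"))
  rec <- table$records
  rec <- rec[!(rec$variant_classification %in% silent_labels), , drop = FALSE]
  out <- lapply(split(rec$gene, rec$instance), function(g) sort(unique(g)))
  # instances appearing only with silent records map to the empty set
  silent_only <- setdiff(unique(table$records$instance), names(out))
  for (i in silent_only) out[[i]] <- character(0)
  out
}

#' Read a plain-text gene list
#'
#' One gene id per line; blank lines and `#` comments are skipped;
#' duplicates are removed keeping the first occurrence.
#'
#' @param path path to the file.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Construct a single patient instance
#'
#' Bundles the three gene sets observed for one patient: genes expressed in
#' the normal sample, genes expressed in the tumor sample, and genes
#' non-silently mutated in the tumor sample.  The sets may overlap
#' arbitrarily; mutated genes need not be expressed.
#'
#' @param id instance (patient) identifier.
#' @param normal_expressed,tumor_expressed,tumor_mutated character vectors
#'   of gene ids.
#' @return an object of class `sample_instance`.
#' @export
sample_instance <- function(id, normal_expressed, tumor_expressed,
                            tumor_mutated = character(0)) {
  structure(
    list(id = as.character(id),
         normal_expressed = unique(as.character(normal_expressed)),
         tumor_expressed = unique(as.character(tumor_expressed)),
         tumor_mutated = unique(as.character(tumor_mutated))),
    class = "sample_instance")
}

#' Assemble patient instances from expression and mutation calls
#'
#' @param expressed output of [call_expressed()].
#' @param mutated output of [call_mutated()]; instances absent from it get
#'   an empty mutated set.
#' @return list of [sample_instance()] objects, in the order of `expressed`.
#' @export
make_instances <- function(expressed, mutated = list()) {
  lapply(names(expressed), function(id) {
    sample_instance(id,
                    normal_expressed = expressed[[id]]$normal,
                    tumor_expressed = expressed[[id]]$tumor,
                    tumor_mutated = if (id %in% names(mutated)) mutated[[id]] else character(0))
  })
}
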