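#' Gene Ontology annotation map
#'
#' Holds per-gene GO term annotations together with the ontology DAG.  The
#' ontology is stored as a directed igraph with edges pointing from child
#' term to parent term; term levels (shortest directed path to a root) are
#' computed lazily by [go_term_levels()].
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param ontology directed acyclic igraph of term ids (child -> parent).
#' @return an object of class `go_annotation`.
#' @export
go_annotation <- function(annotations, ontology) {
  if (!igraph::is_dag(ontology)) {
    stop("ontology validation error: term graph contains a cycle")
  }
  terms <- igraph::V(ontology)$name
  annotations <- lapply(annotations, function(t) sort(unique(as.character(t))))
  unknown <- unique(unlist(lapply(annotations, setdiff, y = terms)))
  if (length(unknown) > 0L) {
    warning(sprintf("dropped annotations to %d term(s) absent from the ontology",
                    length(unknown)))
    annotations <- lapply(annotations, intersect, y = terms)
  }
  structure(list(annotations = annotations, ontology = ontology),
            class = "go_annotation")
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `is_a` and (optionally)
#' `relationship:` edges of the requested types.  Obsolete terms are
#' dropped.  Edges point child -> parent.
#'
#' @param path path to the OBO file.
#' @param relationships relationship types (besides `is_a`) used as parent
#'   edges; default `"part_of"`.
#' @return directed acyclic igraph of term ids.
#' @export
read_obo <- function(path, relationships = "part_of") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  ids <- character(0)
  edges_child <- character(0)
  edges_parent <- character(0)
  bounds <- c(term_starts, length(lines) + 1L)
  for (k in seq_along(term_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk)]
    get1 <- function(key) {
      hit <- chunk[startsWith(chunk, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", hit))
    }
    id <- get1("id")[1L]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", chunk))) next
    ids <- c(ids, id)
    parents <- sub(" *!.*$", "", get1("is_a"))
    for (p in parents) {
      edges_child <- c(edges_child, id)
      edges_parent <- c(edges_parent, p)
    }
    rels <- get1("relationship")
    for (r in rels) {
      fields <- strsplit(trimws(sub(" *!.*$", "", r)), " +")[[1L]]
      if (length(fields) >= 2L && fields[1L] %in% relationships) {
        edges_child <- c(edges_child, id)
        edges_parent <- c(edges_parent, fields[2L])
      }
    }
  }
  keep <- edges_parent %in% ids & edges_child %in% ids
  g <- igraph::make_empty_graph(0, directed = TRUE)
  g <- igraph::add_vertices(g, length(unique(ids)), name = unique(ids))
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(edges_child[keep], edges_parent[keep]))
  }
  if (!igraph::is_dag(g)) stop("ontology validation error: term graph contains a cycle")
  g
}

#' Read a GAF 2.x annotation file
#'
#' Lines starting with `!` are skipped.  By default gene ids are taken from
#' the DB object symbol (column 3) and term ids from column 5.
#'
#' @param path path to the GAF file.
#' @param ontology directed igraph returned by [read_obo()].
#' @param gene_column 1-based column index holding the gene identifier
#'   (default 3, the symbol; use 2 for the DB object id).
#' @return a [go_annotation()] object; annotations to terms absent from the
#'   ontology are dropped with a warning.
#' @export
read_gaf <- function(path, ontology, gene_column = 3L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  ann <- list()
  if (length(lines) > 0L) {
    rows <- strsplit(lines, "\t", fixed = TRUE)
    genes <- vapply(rows, function(r) r[[gene_column]], character(1))
    terms <- vapply(rows, function(r) r[[5L]], character(1))
    ann <- lapply(split(terms, genes), unique)
  }
  go_annotation(ann, ontology)
}

#' Compute GO term levels
#'
#' The level of a term is the length (in edges) of the shortest directed
#' path from the term to an ontology root (a term with no parents); roots
#' are at level 0.
#'
#' @param ontology directed child -> parent igraph.
#' @return named integer vector of levels per term.
#' @export
go_term_levels <- function(ontology) {
  roots <- igraph::V(ontology)[igraph::degree(ontology, mode = "out") == 0]
  d <- igraph::distances(ontology, to = roots, mode = "out")
  lev <- apply(d, 1L, min)
  stats::setNames(as.integer(lev), igraph::V(ontology)$name)
}
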