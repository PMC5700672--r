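#' Construct a measure result
#'
#' A measure result is a per-gene weight map over the node universe plus a
#' sort direction.  Differential (unlabeled) and control measures rank in
#' descending weight order: large absolute change means interesting.
#' Similarity-based (labeled) measures rank ascending: low summed similarity
#' means interesting.
#'
#' @param name measure name, e.g. `"bw"`.
#' @param weights named numeric vector over the universe.
#' @param direction `"descending"` or `"ascending"`.
#' @return object of class `measure_result`.
#' @export
measure_result <- function(name, weights, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  stopifnot(!is.null(names(weights)), !anyNA(weights))
  structure(list(name = name, weights = weights, direction = direction),
            class = "measure_result")
}

#' Ranked gene list of a measure
#'
#' Direction-aware stable sort with a deterministic lexicographic gene-id
#' tie-break, so equal weights always yield the same ordering.
#'
#' @param measure a [measure_result()].
#' @return character vector of gene ids, best-ranked first.
#' @export
ranked_genes <- function(measure) {
  stopifnot(inherits(measure, "measure_result"))
  w <- measure$weights
  g <- names(w)
  ord <- if (measure$direction == "descending") {
    order(-w, g, method = "radix")
  } else {
    order(w, g, method = "radix")
  }
  g[ord]
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf("Measure %s (%s order) over %d genes\n",
              x$name, x$direction, length(x$weights)))
  top <- utils::head(ranked_genes(x), 5L)
  cat("  top:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Write a measure result as a ranked TSV
#'
#' Columns: gene, weight, rank (after the direction-aware sort of
#' [ranked_genes()]).
#'
#' @param measure a [measure_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measure_tsv <- function(measure, path) {
  genes <- ranked_genes(measure)
  df <- data.frame(gene = genes,
                   weight = unname(measure$weights[genes]),
                   rank = seq_along(genes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked measure TSV written by [write_measure_tsv()]
#'
#' @param path input path.
#' @param name measure name; defaults to the file name without extension.
#' @param direction sort direction of the measure.
#' @return a [measure_result()].
#' @export
read_measure_tsv <- function(path, name = NULL,
                             direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  measure_result(name, stats::setNames(df$weight, df$gene), direction)
}
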