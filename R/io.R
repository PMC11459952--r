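#' Read and write count matrices, designs and auxiliary tables
#'
#' Plain TSV interchange: counts as feature-id column plus one column per
#' sample; design as (sample, group, replicate); lengths as
#' (feature_id, length); target pairs as (miRNA, partner_id, partner_class);
#' group summaries as (group, mean, sd, n); qPCR records as
#' (sample, group, target_ct, reference_ct).
#'
#' @param x object to write.
#' @param path file path.
#' @name heatcerna-io
NULL

#' @rdname heatcerna-io
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @param feature_class feature class of the matrix being read.
#' @param lengths optional named length vector to attach.
#' @export
read_counts <- function(path, feature_class = c("lncRNA", "miRNA", "mRNA"),
                        lengths = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, match.arg(feature_class), lengths = lengths)
}

#' @rdname heatcerna-io
#' @export
write_design <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_design(df$sample, df$group, df$replicate)
}

#' @rdname heatcerna-io
#' @export
write_lengths <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"), !is.null(x$lengths))
  utils::write.table(data.frame(feature_id = names(x$lengths),
                                length = as.numeric(x$lengths)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$length, df$feature_id)
}

#' @rdname heatcerna-io
#' @export
write_target_pairs <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
read_target_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- validate_target_pairs(df)
  class(df) <- c("target_pairs", "data.frame")
  df
}

#' @rdname heatcerna-io
#' @export
write_truth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_result"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
write_heat_set <- function(x, path) {
  stopifnot(inherits(x, "heat_specific_set"))
  utils::write.table(x$members, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heatcerna-io
#' @export
read_group_summaries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname heatcerna-io
#' @export
read_qpcr_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a ceRNA network
#'
#' `write_edge_list()` writes a TSV (source, target, edge_type);
#' `write_sif()` the Cytoscape SIF format (`source<TAB>type<TAB>target`);
#' `write_graphml()` GraphML with node `type` attributes (via igraph).
#' `read_edge_list()`, `read_sif()` and `read_graphml()` re-import to the
#' edge data.frame.
#'
#' @param network a [assemble_network()] result.
#' @param path file path.
#' @name cerna-export
NULL

#' @rdname cerna-export
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cerna-export
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname cerna-export
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  e <- network$edges
  writeLines(paste(e$source, e$edge_type, e$target, sep = "\t"), path)
  invisible(path)
}

#' @rdname cerna-export
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(source = vapply(parts, `[[`, character(1), 1),
                   target = vapply(parts, `[[`, character(1), 3),
                   edge_type = vapply(parts, `[[`, character(1), 2),
                   stringsAsFactors = FALSE)
  df
}

#' @rdname cerna-export
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "edge_type")],
    directed = TRUE,
    vertices = network$nodes[, c("id", "type")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname cerna-export
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  data.frame(source = e$from, target = e$to, edge_type = e$edge_type,
             stringsAsFactors = FALSE)
}

#' @rdname cerna-export
#' @param top_k hub table size in the JSON summary.
#' @export
write_network_summary <- function(network, path, top_k = 10L) {
  jsonlite::write_json(network_summary(network, top_k), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
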