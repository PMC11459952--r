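#' Gene-set collection
#'
#' Holds term-to-gene annotations (GO/KEGG style) for over-representation
#' analysis. The default universe is the union of all term members; the paper
#' context supplies no explicit background, so callers may override it in
#' [enrich()].
#'
#' @param sets named list of character vectors (term id -> member gene ids).
#' @param descriptions optional named character vector of term names.
#' @param category optional named character vector of category tags (e.g. BP,
#'   KEGG).
#' @param universe optional character vector of background gene ids; must
#'   contain every member.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, category = NULL,
                                universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("'sets' must be a uniquely named list", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) {
    stop("empty term(s): ", paste(names(sets)[lengths(sets) == 0], collapse = ", "),
         call. = FALSE)
  }
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members)
  } else {
    universe <- unique(as.character(universe))
    out <- setdiff(members, universe)
    if (length(out)) {
      stop("term members outside the universe: ",
           paste(utils::head(out, 10), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sets = sets,
                 descriptions = descriptions %||% stats::setNames(names(sets), names(sets)),
                 category = category,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: one term per line as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
                     call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one query hit, computes the inclusive
#' upper-tail hypergeometric P-value of the overlap between the query and the
#' term, Benjamini-Hochberg adjusted across all terms in the collection.
#' Query ids outside the universe are dropped with a warning. Results are
#' sorted by raw P ascending, ties broken by term id; ranking by raw P
#' mirrors the conventional "top pathways" display.
#'
#' @param query character vector of gene ids (e.g. ceRNA-network mRNAs).
#' @param collection a [gene_set_collection()].
#' @param universe optional background override (default: the collection's).
#' @return data.frame of class `enrichment_result` with columns term, name,
#'   k, K, n, N, fold_enrichment, pvalue, padj; attribute `n_dropped` counts
#'   query ids outside the universe.
#' @export
enrich <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe %||% collection$universe)
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query id(s) outside the universe were dropped")
    query <- intersect(query, universe)
  }
  n <- length(query); N <- length(universe)
  if (n == 0) {
    warning("empty query after universe filtering")
    res <- empty_enrichment()
    attr(res, "n_dropped") <- length(outside)
    return(res)
  }
  terms <- names(collection$sets)
  K <- vapply(collection$sets, function(s) length(intersect(s, universe)), integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")    # across all tested terms
  keep <- k >= 1
  if (!any(keep)) {
    res <- empty_enrichment()
    attr(res, "n_dropped") <- length(outside)
    return(res)
  }
  res <- data.frame(term = terms[keep],
                    name = unname(collection$descriptions[terms[keep]]),
                    k = k[keep], K = K[keep], n = n, N = N,
                    fold_enrichment = (k[keep] / n) / (K[keep] / N),
                    pvalue = p[keep], padj = padj[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(res$pvalue, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "n_dropped") <- length(outside)
  res
}

empty_enrichment <- function() {
  res <- data.frame(term = character(0), name = character(0), k = integer(0),
                    K = integer(0), n = integer(0), N = integer(0),
                    fold_enrichment = numeric(0), pvalue = numeric(0),
                    padj = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Top enriched terms
#'
#' @param results an [enrich()] result (already sorted by raw P).
#' @param k number of terms to return (default 20, the conventional display).
#' @return the first `k` rows (fewer if not available).
#' @export
top_terms <- function(results, k = 20L) {
  stopifnot(inherits(results, "enrichment_result"))
  utils::head(results, max(0L, k))
}
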