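#' Correlation edges (Spearman / Pearson)
#'
#' `spearman()` computes the Spearman rank correlation (Pearson correlation of
#' mid-ranks, average ranks for ties); `pearson()` the product-moment
#' correlation. Both return a `cor_edge` carrying the endpoint ids, the
#' coefficient and the sample count. Zero variance in either vector yields an
#' undefined correlation (`value = NA`, `ok = FALSE`) which downstream
#' filtering excludes.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @param a,b endpoint ids recorded on the edge.
#' @return a list of class `cor_edge` with fields `a`, `b`, `type`
#'   (`"SCC"`/`"PCC"`), `value`, `n`, `ok`.
#' @export
spearman <- function(x, y, a = "x", b = "y") {
  cor_edge_compute(x, y, a, b, "SCC")
}

#' @rdname spearman
#' @export
pearson <- function(x, y, a = "x", b = "y") {
  cor_edge_compute(x, y, a, b, "PCC")
}

cor_edge_compute <- function(x, y, a, b, type) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3) stop("correlation requires at least 3 paired samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("correlation inputs must be finite", call. = FALSE)
  }
  if (type == "SCC") { x <- rank(x); y <- rank(y) }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    val <- NA_real_; ok <- FALSE
  } else {
    val <- stats::cor(x, y); ok <- TRUE
  }
  structure(list(a = a, b = b, type = type, value = val, n = length(x), ok = ok),
            class = "cor_edge")
}

#' @export
print.cor_edge <- function(x, ...) {
  cat(sprintf("<cor_edge> %s(%s, %s) = %s (n = %d)\n", x$type, x$a, x$b,
              if (x$ok) sprintf("%.4f", x$value) else "undefined", x$n))
  invisible(x)
}

#' Hypergeometric shared-sponge test
#'
#' Tests whether a lncRNA and an mRNA share more predicted miRNA regulators
#' than expected by chance, the criterion for a competing-endogenous-RNA
#' relationship. With `N = |universe|`, `K = |lnc_targets|`,
#' `n = |mrna_targets|` and `k` the observed overlap, the P-value is the
#' inclusive upper tail `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param lnc_targets,mrna_targets character vectors of predicted miRNA ids
#'   for the lncRNA and the mRNA; must be subsets of `universe`.
#' @param universe character vector: the miRNA background (all miRNAs with
#'   target predictions).
#' @return the P-value.
#' @export
sponge_test <- function(lnc_targets, mrna_targets, universe) {
  universe <- unique(universe)
  lnc_targets <- unique(lnc_targets)
  mrna_targets <- unique(mrna_targets)
  if (length(universe) < 1) stop("'universe' must be non-empty", call. = FALSE)
  bad <- c(setdiff(lnc_targets, universe), setdiff(mrna_targets, universe))
  if (length(bad)) {
    stop("target ids outside the universe: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe); K <- length(lnc_targets); n <- length(mrna_targets)
  k <- length(intersect(lnc_targets, mrna_targets))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' ceRNA triplet assembly
#'
#' Builds candidate lncRNA-miRNA-mRNA triplets from heat-specific lncRNAs,
#' predicted miRNA-target pairs and the three expression matrices. A triplet
#' (lncRNA, mRNA, shared miRNAs) is retained when (i) the hypergeometric
#' shared-sponge test on the predicted target sets gives `P < alpha`,
#' (ii) the lncRNA-mRNA Pearson correlation exceeds `pcc_threshold`
#' (strictly), and (iii) at least one shared miRNA has Spearman correlation
#' below `scc_threshold` (strictly) with both the lncRNA and the mRNA; only
#' such miRNAs are retained in the triplet. Correlations are computed on
#' log2(FPKM + 1) across all samples shared by the matrices.
#'
#' @param lnc_expr,mirna_expr,mrna_expr [expression_matrix()] objects over the
#'   same sample universe.
#' @param pairs a `target_pairs` data.frame (miRNA, partner_id, partner_class).
#' @param heat_set a [venn_filter()] result (or data.frame with a `feature`
#'   column) giving the lncRNAs admitted to the network.
#' @param scc_threshold retain miRNA legs with SCC strictly below this
#'   (default -0.7).
#' @param pcc_threshold retain lncRNA-mRNA pairs with PCC strictly above this
#'   (default 0.9).
#' @param alpha sponge-test significance level (default 0.05, raw P).
#' @param sponge_on whether the hypergeometric test is applied to the
#'   correlation-`"supported"` target sets (default: predicted targets whose
#'   miRNA leg passes the SCC threshold against that partner) or to the raw
#'   `"predicted"` sets. Sparse in-silico target lists carry unsupported
#'   predictions whose inclusion makes the sponge test's power depend on
#'   prediction noise rather than on the expression evidence; the supported
#'   variant conditions the test on the same evidence the network uses.
#' @return an object of class `cerna_triplets`: list with `triplets` (list of
#'   records: lncRNA, mRNA, mirnas, pcc, scc_lnc, scc_mrna, sponge_p),
#'   `thresholds`, and `n_excluded_undefined` (candidate legs dropped for
#'   zero-variance correlations). Triplets are ordered lexicographically by
#'   (lncRNA, mRNA).
#' @export
build_triplets <- function(lnc_expr, mirna_expr, mrna_expr, pairs, heat_set,
                           scc_threshold = -0.7, pcc_threshold = 0.9,
                           alpha = 0.05, sponge_on = c("supported", "predicted")) {
  sponge_on <- match.arg(sponge_on)
  for (m in list(lnc_expr, mirna_expr, mrna_expr)) stopifnot(inherits(m, "expr_matrix"))
  samples <- colnames(lnc_expr$values)
  if (!setequal(samples, colnames(mirna_expr$values)) ||
      !setequal(samples, colnames(mrna_expr$values))) {
    stop("expression matrices do not share a sample universe", call. = FALSE)
  }
  pairs <- validate_target_pairs(pairs)
  members <- if (inherits(heat_set, "heat_specific_set")) heat_set$members else heat_set
  lnc_ids <- members$feature
  missing_lnc <- setdiff(lnc_ids, rownames(lnc_expr$values))
  if (length(missing_lnc)) {
    stop("heat-specific lncRNAs absent from expression matrix: ",
         paste(missing_lnc, collapse = ", "), call. = FALSE)
  }
  if (length(samples) == 0 || nrow(pairs) == 0 || length(lnc_ids) == 0) {
    warning("empty candidate universe; no triplets built")
    return(structure(list(triplets = list(),
                          thresholds = c(scc = scc_threshold, pcc = pcc_threshold,
                                         alpha = alpha),
                          n_excluded_undefined = 0L),
                     class = "cerna_triplets"))
  }

  lnc_log <- log_expression(lnc_expr)[, samples, drop = FALSE]
  mir_log <- log_expression(mirna_expr)[, samples, drop = FALSE]
  mrna_log <- log_expression(mrna_expr)[, samples, drop = FALSE]

  universe <- unique(pairs$miRNA)
  tgt <- split(pairs$miRNA, pairs$partner_id)
  lp <- pairs[pairs$partner_class == "lncRNA", , drop = FALSE]
  mp <- pairs[pairs$partner_class == "mRNA", , drop = FALSE]
  lnc_tgt <- split(lp$miRNA, lp$partner_id)
  mrna_tgt <- split(mp$miRNA, mp$partner_id)

  cand_lnc <- sort(intersect(lnc_ids, names(lnc_tgt)))
  cand_mrna <- sort(intersect(names(mrna_tgt), rownames(mrna_log)))
  cand_mir <- sort(intersect(universe, rownames(mir_log)))
  n_undef <- 0L

  # SCC of every candidate partner against every expressed miRNA in the pair
  # list; zero-variance vectors yield NA (undefined, excluded with a count)
  scc_against_mirs <- function(mat, ids) {
    if (!length(ids) || !length(cand_mir)) {
      return(matrix(NA_real_, length(ids), length(cand_mir),
                    dimnames = list(ids, cand_mir)))
    }
    suppressWarnings(stats::cor(t(mat[ids, , drop = FALSE]),
                                t(mir_log[cand_mir, , drop = FALSE]),
                                method = "spearman"))
  }
  scc_lnc_mat <- scc_against_mirs(lnc_log, cand_lnc)
  scc_mrna_mat <- scc_against_mirs(mrna_log, cand_mrna)
  supported <- function(ids_targets, scc_mat, id) {
    tg <- intersect(unique(ids_targets), cand_mir)
    v <- scc_mat[id, tg]
    n_undef <<- n_undef + sum(is.na(v))
    tg[!is.na(v) & v < scc_threshold]
  }
  lt_sup_all <- stats::setNames(
    lapply(cand_lnc, function(l) supported(lnc_tgt[[l]], scc_lnc_mat, l)), cand_lnc)
  mt_sup_all <- stats::setNames(
    lapply(cand_mrna, function(m) supported(mrna_tgt[[m]], scc_mrna_mat, m)), cand_mrna)

  triplets <- list()
  for (l in cand_lnc) {
    lt <- unique(lnc_tgt[[l]])
    lt_sup <- lt_sup_all[[l]]
    lvec <- lnc_log[l, ]
    for (m in cand_mrna) {
      mt <- unique(mrna_tgt[[m]])
      if (!length(intersect(lt, mt))) next
      mt_sup <- mt_sup_all[[m]]
      p <- if (sponge_on == "supported") sponge_test(lt_sup, mt_sup, universe)
           else sponge_test(lt, mt, universe)
      if (!(p < alpha)) next
      pe <- pearson(lvec, mrna_log[m, ], a = l, b = m)
      if (!pe$ok) { n_undef <- n_undef + 1L; next }
      if (!(pe$value > pcc_threshold)) next
      keep <- sort(intersect(lt_sup, mt_sup))
      if (!length(keep)) next
      scc_l <- scc_lnc_mat[l, keep]; scc_m <- scc_mrna_mat[m, keep]
      names(scc_l) <- keep; names(scc_m) <- keep
      triplets[[length(triplets) + 1L]] <-
        list(lncRNA = l, mRNA = m, mirnas = keep, pcc = pe$value,
             scc_lnc = scc_l, scc_mrna = scc_m, sponge_p = p)
    }
  }
  structure(list(triplets = triplets,
                 thresholds = c(scc = scc_threshold, pcc = pcc_threshold,
                                alpha = alpha),
                 n_excluded_undefined = n_undef),
            class = "cerna_triplets")
}

validate_target_pairs <- function(pairs) {
  req <- c("miRNA", "partner_id", "partner_class")
  if (!all(req %in% names(pairs))) {
    stop("target pairs need columns miRNA, partner_id, partner_class", call. = FALSE)
  }
  if (!all(pairs$partner_class %in% c("lncRNA", "mRNA"))) {
    stop("partner_class must be 'lncRNA' or 'mRNA'", call. = FALSE)
  }
  key <- paste(pairs$miRNA, pairs$partner_id)
  if (anyDuplicated(key)) {
    stop("duplicate miRNA-partner pairs in target pair list", call. = FALSE)
  }
  cls <- tapply(pairs$partner_class, pairs$partner_id, function(x) length(unique(x)))
  if (any(cls > 1)) {
    stop("inconsistent partner_class for partner id(s): ",
         paste(names(cls)[cls > 1], collapse = ", "), call. = FALSE)
  }
  pairs
}

#' @export
print.cerna_triplets <- function(x, ...) {
  cat(sprintf("<cerna_triplets> %d triplets (SCC < %g, PCC > %g, sponge P < %g)\n",
              length(x$triplets), x$thresholds["scc"], x$thresholds["pcc"],
              x$thresholds["alpha"]))
  invisible(x)
}

#' @export
as.data.frame.cerna_triplets <- function(x, ...) {
  if (!length(x$triplets)) {
    return(data.frame(lncRNA = character(0), miRNA = character(0),
                      mRNA = character(0), pcc = numeric(0),
                      scc_lnc = numeric(0), scc_mrna = numeric(0),
                      sponge_p = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$triplets, function(t) {
    data.frame(lncRNA = t$lncRNA, miRNA = t$mirnas, mRNA = t$mRNA,
               pcc = t$pcc, scc_lnc = unname(t$scc_lnc),
               scc_mrna = unname(t$scc_mrna), sponge_p = t$sponge_p,
               stringsAsFactors = FALSE)
  }))
}

#' Assemble the typed ceRNA network from triplets
#'
#' Deduplicates the lncRNA-miRNA and miRNA-mRNA relationship pairs implied by
#' a set of triplets into a typed node/edge graph with per-node degrees.
#'
#' @param triplets a [build_triplets()] result (or a list of triplet records).
#' @return an object of class `cerna_network`: list with `nodes` (data.frame
#'   id/type/degree), `edges` (data.frame source/target/edge_type; source is
#'   the lncRNA or miRNA), and `edge_counts` by type.
#' @export
assemble_network <- function(triplets) {
  tl <- if (inherits(triplets, "cerna_triplets")) triplets$triplets else triplets
  edges <- list()
  for (t in tl) {
    for (mi in t$mirnas) {
      edges[[length(edges) + 1L]] <-
        data.frame(source = t$lncRNA, target = mi, edge_type = "lncRNA-miRNA",
                   stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <-
        data.frame(source = mi, target = t$mRNA, edge_type = "miRNA-mRNA",
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(0), target = character(0),
               edge_type = character(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$edge_type, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  lm <- edges$edge_type == "lncRNA-miRNA"
  lnc_nodes <- unique(edges$source[lm])
  mir_nodes <- unique(c(edges$target[lm], edges$source[!lm]))
  mrna_nodes <- unique(edges$target[!lm])
  nodes <- data.frame(
    id = c(lnc_nodes, mir_nodes, mrna_nodes),
    type = rep(c("lncRNA", "miRNA", "mRNA"),
               c(length(lnc_nodes), length(mir_nodes), length(mrna_nodes))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  deg <- table(factor(c(edges$source, edges$target), levels = nodes$id))
  nodes$degree <- as.integer(deg[nodes$id])
  rownames(nodes) <- NULL
  out <- list(nodes = nodes, edges = edges,
              edge_counts = table(factor(edges$edge_type,
                                         levels = c("lncRNA-miRNA", "miRNA-mRNA"))))
  class(out) <- "cerna_network"
  out
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes, %d edges (%d lncRNA-miRNA, %d miRNA-mRNA)\n",
              nrow(x$nodes), nrow(x$edges),
              x$edge_counts["lncRNA-miRNA"], x$edge_counts["miRNA-mRNA"]))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param network a [assemble_network()] result.
#' @param top_k number of nodes to return.
#' @return data.frame (id, type, degree) sorted by degree descending, ties
#'   broken lexicographically by id.
#' @export
rank_hubs <- function(network, top_k = 10L) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$nodes) == 0) {
    warning("empty network; no hubs")
    return(network$nodes)
  }
  nd <- network$nodes
  nd <- nd[order(-nd$degree, nd$id), , drop = FALSE]
  rownames(nd) <- NULL
  utils::head(nd, top_k)
}

#' Network summary
#'
#' @param network a `cerna_network`.
#' @param top_k hub table size.
#' @return list with node/edge counts by type and the hub table.
#' @export
network_summary <- function(network, top_k = 10L) {
  stopifnot(inherits(network, "cerna_network"))
  list(n_nodes = nrow(network$nodes),
       nodes_by_type = as.list(table(network$nodes$type)),
       n_edges = nrow(network$edges),
       edges_by_type = as.list(network$edge_counts),
       hubs = if (nrow(network$nodes)) rank_hubs(network, top_k) else network$nodes)
}
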