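#' Run the full heat-specific ceRNA screen on a dataset
#'
#' Convenience wrapper chaining the stages: the three pairwise DE contrasts
#' on the lncRNA counts, the pair-fed Venn screen, and (when target pairs are
#' supplied) ceRNA triplet assembly and network construction.
#'
#' @param lnc_expr,mirna_expr,mrna_expr [expression_matrix()] objects of raw
#'   counts; `mirna_expr`/`mrna_expr` may be NULL to stop after the Venn
#'   screen.
#' @param design a [sample_design()].
#' @param pairs optional `target_pairs` data.frame.
#' @param alpha,fc_threshold DE thresholds (defaults 0.05 and 1.5).
#' @param scc_threshold,pcc_threshold,sponge_alpha network thresholds
#'   (defaults -0.7, 0.9, 0.05).
#' @param exclude_nc_pf Venn definition flag, see [venn_filter()].
#' @return list of class `chs_screen` with `de` (the three `de_result`s),
#'   `heat_set`, and when pairs are given `triplets` and `network`.
#' @export
run_chs_screen <- function(lnc_expr, design, mirna_expr = NULL, mrna_expr = NULL,
                           pairs = NULL, alpha = 0.05, fc_threshold = 1.5,
                           scc_threshold = -0.7, pcc_threshold = 0.9,
                           sponge_alpha = 0.05, exclude_nc_pf = TRUE) {
  de <- list(
    HS_vs_NC = differential_expression(lnc_expr, design, c("HS", "NC"),
                                       alpha = alpha, fc_threshold = fc_threshold),
    HS_vs_PF = differential_expression(lnc_expr, design, c("HS", "PF"),
                                       alpha = alpha, fc_threshold = fc_threshold),
    NC_vs_PF = differential_expression(lnc_expr, design, c("NC", "PF"),
                                       alpha = alpha, fc_threshold = fc_threshold))
  heat_set <- venn_filter(de$HS_vs_NC, de$HS_vs_PF, de$NC_vs_PF,
                          exclude_nc_pf = exclude_nc_pf)
  out <- list(de = de, heat_set = heat_set)
  if (!is.null(pairs) && !is.null(mirna_expr) && !is.null(mrna_expr) &&
      nrow(heat_set$members) > 0) {
    out$triplets <- build_triplets(lnc_expr, mirna_expr, mrna_expr, pairs,
                                   heat_set, scc_threshold = scc_threshold,
                                   pcc_threshold = pcc_threshold,
                                   alpha = sponge_alpha)
    out$network <- assemble_network(out$triplets)
  }
  class(out) <- "chs_screen"
  out
}

#' @export
print.chs_screen <- function(x, ...) {
  for (d in x$de) print(d)
  print(x$heat_set)
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}

#' Sensitivity and precision of a recovered set against ground truth
#'
#' @param recovered character vector of recovered ids (or data.frame with a
#'   `feature` column).
#' @param truth character vector of planted ids.
#' @return named numeric: `sensitivity` (recall), `precision`, `tp`, `fp`,
#'   `fn`. Precision of an empty recovery is reported as NA.
#' @export
recovery_metrics <- function(recovered, truth) {
  if (is.data.frame(recovered)) recovered <- recovered$feature
  recovered <- unique(recovered); truth <- unique(truth)
  tp <- length(intersect(recovered, truth))
  fp <- length(setdiff(recovered, truth))
  fn <- length(setdiff(truth, recovered))
  c(sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
    precision = if (length(recovered)) tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn)
}

#' Triplet recovery metrics
#'
#' Compares recovered (lncRNA, miRNA, mRNA) triplets against the planted
#' ones, matching on the full triplet identity.
#'
#' @param triplets a [build_triplets()] result.
#' @param truth_triplets data.frame with columns lncRNA, miRNA, mRNA.
#' @return as [recovery_metrics()].
#' @export
triplet_recovery <- function(triplets, truth_triplets) {
  df <- as.data.frame(triplets)
  rec <- if (nrow(df)) paste(df$lncRNA, df$miRNA, df$mRNA) else character(0)
  tru <- paste(truth_triplets$lncRNA, truth_triplets$miRNA, truth_triplets$mRNA)
  m <- recovery_metrics(rec, tru)
  m
}
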