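#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across features of
#' the ratio of a sample's count to the feature's geometric mean, using only
#' features with a nonzero geometric mean (i.e. no zero count in any sample).
#'
#' @param counts numeric count matrix (features x samples).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "expr_matrix")) counts <- counts$values
  logs <- log(counts)
  logmean <- rowMeans(logs)
  use <- is.finite(logmean)
  if (!any(use)) stop("no feature has a nonzero geometric mean; cannot normalize",
                      call. = FALSE)
  sf <- apply(logs[use, , drop = FALSE], 2, function(lc) {
    exp(stats::median(lc - logmean[use]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factor(s) computed", call. = FALSE)
  }
  sf
}

# method-of-moments per-feature NB dispersion on normalized counts, shrunk
# toward a fitted a0 + a1/mean trend (equal-weight average on the raw scale)
estimate_dispersions <- function(norm, groups, inv_sf) {
  lev <- unique(groups)
  nfeat <- nrow(norm)
  alpha_raw <- rep(NA_real_, nfeat)
  mu_all <- rowMeans(norm)
  num <- rep(0, nfeat); den <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    q <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    cg <- mean(inv_sf[idx])
    a <- ifelse(q > 0, (v - q * cg) / q^2, NA_real_)
    w <- ng - 1
    num <- num + ifelse(is.na(a), 0, w * a)
    den <- den + w
  }
  alpha_raw <- num / den
  alpha_pos <- pmax(alpha_raw, 1e-8)
  fit_ok <- is.finite(alpha_raw) & alpha_raw > 0 & mu_all > 0
  if (sum(fit_ok) >= 10) {
    tf <- stats::lm(alpha_raw[fit_ok] ~ I(1 / mu_all[fit_ok]))
    a0 <- max(stats::coef(tf)[1], 1e-8)
    a1 <- max(stats::coef(tf)[2], 0)
  } else {
    a0 <- max(stats::median(alpha_raw[fit_ok], na.rm = TRUE), 1e-8)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  alpha_trend <- a0 + a1 / pmax(mu_all, 1e-8)
  alpha <- 0.5 * alpha_pos + 0.5 * alpha_trend
  alpha[!is.finite(alpha)] <- alpha_trend[!is.finite(alpha)]
  pmax(alpha, 1e-8)
}

#' Negative-binomial differential expression for one group contrast
#'
#' A self-contained NB pipeline in the DESeq2 mould: median-of-ratios size
#' factors (computed over all samples in the matrix), per-feature
#' method-of-moments dispersion shrunk toward a fitted mean-dispersion trend,
#' and a Wald test on the log fold change between the two contrast groups.
#' A feature is flagged DE when `P < alpha` and `|FC| >= fc_threshold`
#' (equivalently `|log2FC| >= log2(fc_threshold)`).
#'
#' @param x an [expression_matrix()] of raw counts.
#' @param design a [sample_design()] covering the samples of `x`.
#' @param contrast character of length 2: numerator group, denominator group.
#' @param alpha significance level in (0, 1) applied to raw P-values (the
#'   conventional screen for this design); set `adjust = TRUE` to flag on
#'   Benjamini-Hochberg adjusted P instead.
#' @param fc_threshold linear-scale absolute fold-change threshold (>= 1).
#' @param adjust logical; flag on BH-adjusted P-values.
#' @return an object of class `de_result`: a list with `table` (data.frame:
#'   feature, mean per group, log2fc, pvalue, padj, de, direction), `contrast`
#'   label (e.g. `"HS_vs_NC"`), `alpha`, `fc_threshold`.
#' @export
differential_expression <- function(x, design, contrast, alpha = 0.05,
                                    fc_threshold = 1.5, adjust = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!all(contrast %in% design$group)) {
    stop("unknown group label(s): ",
         paste(setdiff(contrast, design$group), collapse = ", "), call. = FALSE)
  }
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("'contrast' must name two distinct groups", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1", call. = FALSE)
  counts <- x$values
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  if (anyNA(design$sample)) stop("design does not cover all samples", call. = FALSE)
  grp <- design$group
  for (g in contrast) {
    if (sum(grp == g) < 2) stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  inv_sf <- 1 / sf

  sel <- grp %in% contrast
  alpha_disp <- estimate_dispersions(norm[, sel, drop = FALSE], grp[sel], inv_sf[sel])

  i1 <- which(grp == contrast[1]); i2 <- which(grp == contrast[2])
  q1 <- rowMeans(norm[, i1, drop = FALSE]); q2 <- rowMeans(norm[, i2, drop = FALSE])
  n1 <- length(i1); n2 <- length(i2)
  pseudo <- 0.5
  q1a <- q1 + pseudo; q2a <- q2 + pseudo
  lfc <- log2(q1a / q2a)
  # Var(mean of K/s) = q * sum(1/s)/n^2 + alpha * q^2 / n; on the log scale
  # divide by q^2
  vlog1 <- (sum(inv_sf[i1]) / n1^2) / q1a + alpha_disp / n1
  vlog2 <- (sum(inv_sf[i2]) / n2^2) / q2a + alpha_disp / n2
  z <- (lfc * log(2)) / sqrt(vlog1 + vlog2)
  pval <- 2 * stats::pnorm(-abs(z))
  allzero <- q1 == 0 & q2 == 0
  lfc[allzero] <- 0
  pval[allzero] <- 1
  padj <- stats::p.adjust(pval, method = "BH")
  p_used <- if (adjust) padj else pval
  de <- p_used < alpha & abs(lfc) >= log2(fc_threshold)
  de[allzero] <- FALSE
  direction <- ifelse(de & lfc > 0, "up", ifelse(de & lfc < 0, "down", "ns"))
  tab <- data.frame(feature = rownames(counts),
                    mean_num = q1, mean_den = q2,
                    log2fc = lfc, pvalue = pval, padj = padj,
                    de = de, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[2:3] <- paste0("mean_", contrast)
  out <- list(table = tab, contrast = paste0(contrast[1], "_vs_", contrast[2]),
              groups = contrast, alpha = alpha, fc_threshold = fc_threshold,
              adjusted = adjust, feature_class = x$feature_class)
  class(out) <- "de_result"
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s (%s): %d features, %d DE (%d up, %d down) at P<%g, |FC|>=%g%s\n",
              x$contrast, x$feature_class, nrow(x$table), sum(x$table$de),
              sum(x$table$direction == "up"), sum(x$table$direction == "down"),
              x$alpha, x$fc_threshold, if (x$adjusted) " (BH)" else ""))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  s <- list(contrast = object$contrast, n = nrow(object$table),
            n_de = sum(object$table$de),
            n_up = sum(object$table$direction == "up"),
            n_down = sum(object$table$direction == "down"))
  class(s) <- "summary.de_result"
  s
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d DE (%d up, %d down)\n", x$contrast, x$n_de, x$n, x$n_up, x$n_down))
  invisible(x)
}

de_sets <- function(res) {
  stopifnot(inherits(res, "de_result"))
  t <- res$table
  list(up = t$feature[t$direction == "up"],
       down = t$feature[t$direction == "down"],
       de = t$feature[t$de])
}

#' Pair-fed Venn screen for heat-specific lncRNAs
#'
#' Isolates features whose differential expression is attributable to high
#' temperature rather than reduced feed intake: a feature is heat-specific
#' when it is DE with consistent direction in both HS-vs-NC and HS-vs-PF and
#' (by default) not DE in the NC-vs-PF contrast, which captures pure
#' feed-intake effects via the pair-fed control.
#'
#' @param hs_nc,hs_pf,nc_pf [differential_expression()] results for the
#'   HS-vs-NC, HS-vs-PF and NC-vs-PF contrasts over the same feature universe.
#' @param exclude_nc_pf logical; drop members that are DE in NC-vs-PF
#'   (default TRUE). With FALSE the screen is the pure two-set intersection.
#' @return an object of class `heat_specific_set`: list with `members`
#'   (data.frame feature/direction), `n_up`, `n_down`, `provenance` (the three
#'   contrast labels) and `exclude_nc_pf`.
#' @export
venn_filter <- function(hs_nc, hs_pf, nc_pf, exclude_nc_pf = TRUE) {
  for (r in list(hs_nc, hs_pf, nc_pf)) stopifnot(inherits(r, "de_result"))
  u1 <- hs_nc$table$feature; u2 <- hs_pf$table$feature; u3 <- nc_pf$table$feature
  if (!setequal(u1, u2) || !setequal(u1, u3)) {
    miss <- unique(c(setdiff(u1, u2), setdiff(u2, u1),
                     setdiff(u1, u3), setdiff(u3, u1)))
    stop("feature universes differ between contrasts; offending ids: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10) else "",
         call. = FALSE)
  }
  s1 <- de_sets(hs_nc); s2 <- de_sets(hs_pf); s3 <- de_sets(nc_pf)
  up <- intersect(s1$up, s2$up)
  down <- intersect(s1$down, s2$down)
  if (exclude_nc_pf) {
    up <- setdiff(up, s3$de)
    down <- setdiff(down, s3$de)
  }
  members <- data.frame(feature = c(sort(up), sort(down)),
                        direction = rep(c("up", "down"), c(length(up), length(down))),
                        stringsAsFactors = FALSE)
  out <- list(members = members, n_up = length(up), n_down = length(down),
              provenance = c(hs_nc$contrast, hs_pf$contrast, nc_pf$contrast),
              exclude_nc_pf = exclude_nc_pf)
  class(out) <- "heat_specific_set"
  out
}

#' @export
print.heat_specific_set <- function(x, ...) {
  cat(sprintf("<heat_specific_set> %d lncRNAs (%d up, %d down) from %s\n",
              nrow(x$members), x$n_up, x$n_down,
              paste(x$provenance, collapse = ", ")))
  invisible(x)
}
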