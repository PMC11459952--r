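#' Expression matrix container
#'
#' A light container for a feature-by-sample expression matrix of one feature
#' class (lncRNA, miRNA or mRNA), optionally carrying per-feature transcript
#' lengths for FPKM normalization.
#'
#' @param values numeric matrix, rows = features, columns = samples; must have
#'   unique row and column names and no negative entries. Raw counts should be
#'   integer-valued.
#' @param feature_class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @param lengths optional named numeric vector of transcript lengths in
#'   nucleotides covering the features.
#' @param units `"counts"` or `"FPKM"`; what `values` holds.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, feature_class = c("lncRNA", "miRNA", "mRNA"),
                              lengths = NULL, units = c("counts", "FPKM")) {
  feature_class <- match.arg(feature_class)
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(values)]
    if (anyNA(lengths)) {
      missing <- rownames(values)[is.na(lengths)]
      stop("missing length for feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
    names(lengths) <- rownames(values)
  }
  structure(list(values = values, feature_class = feature_class,
                 lengths = lengths, units = units),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples (%s)\n",
              x$feature_class, nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample design table
#'
#' Validates a sample-to-group assignment for the three-group chronic heat
#' stress design (NC = normal control, HS = heat stress, PF = pair-fed).
#'
#' @param sample character vector of unique sample ids.
#' @param group character vector of group labels (subset of NC/HS/PF).
#' @param replicate integer replicate index within group.
#' @return a `data.frame` with class `sample_design`.
#' @export
sample_design <- function(sample, group, replicate = NULL) {
  if (anyDuplicated(sample)) stop("duplicate sample ids in design", call. = FALSE)
  if (!all(group %in% c("NC", "HS", "PF"))) {
    stop("group labels must be among NC, HS, PF", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- stats::ave(seq_along(sample), group, FUN = seq_along)
  d <- data.frame(sample = as.character(sample), group = as.character(group),
                  replicate = as.integer(replicate), stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[f, s] = count[f, s] * 1e9 / (total_counts[s] * length[f])`.
#'
#' @param x an [expression_matrix()] of raw counts.
#' @param lengths optional named length vector overriding `x$lengths`.
#' @return an `expr_matrix` in FPKM units.
#' @export
fpkm <- function(x, lengths = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$units == "FPKM") return(x)
  lengths <- lengths %||% x$lengths
  if (is.null(lengths)) stop("feature lengths are required for FPKM", call. = FALSE)
  lengths <- lengths[rownames(x$values)]
  if (anyNA(lengths)) {
    stop("missing length for feature(s): ",
         paste(rownames(x$values)[is.na(lengths)], collapse = ", "), call. = FALSE)
  }
  depth <- colSums(x$values)
  if (any(depth <= 0)) {
    stop("zero sequencing depth in sample(s): ",
         paste(colnames(x$values)[depth <= 0], collapse = ", "), call. = FALSE)
  }
  vals <- sweep(x$values, 2, depth, "/")
  vals <- sweep(vals, 1, as.numeric(lengths), "/") * 1e9
  expression_matrix(vals, x$feature_class, lengths = lengths, units = "FPKM")
}

# log2-scale expression used for PCA and co-expression: log2(FPKM + 1) when
# lengths are available, otherwise log2(CPM + 1) (depth-only normalization)
log_expression <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$units == "FPKM") return(log2(x$values + 1))
  if (!is.null(x$lengths)) return(log2(fpkm(x)$values + 1))
  depth <- colSums(x$values)
  if (any(depth <= 0)) {
    stop("zero sequencing depth in sample(s): ",
         paste(colnames(x$values)[depth <= 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(x$values, 2, depth / 1e6, "/") + 1)
}

#' Principal component report for sample-level quality control
#'
#' Computes a PCA of the samples on log2(FPKM + 1) values and reports the
#' fraction of variance explained per component together with sample scores.
#' Used to confirm that the dominant axis of variation separates the
#' experimental groups.
#'
#' @param x an [expression_matrix()].
#' @param design optional [sample_design()]; group labels are attached to the
#'   scores when given.
#' @return a list of class `pca_report` with `variance_explained` (fractions
#'   summing to 1, sorted descending), `scores` (samples x components) and
#'   `degenerate` (TRUE when the samples carry no variance).
#' @export
pca_report <- function(x, design = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  lm <- log_expression(x)
  sv <- t(lm)                       # samples x features
  sv <- scale(sv, center = TRUE, scale = FALSE)
  total <- sum(sv^2)
  if (total <= .Machine$double.eps * length(sv)) {
    warning("degenerate input: samples are identical; variance fractions undefined")
    k <- min(dim(sv))
    out <- list(variance_explained = rep(0, k),
                scores = matrix(0, nrow(sv), k,
                                dimnames = list(rownames(sv), paste0("PC", seq_len(k)))),
                degenerate = TRUE, design = design)
    class(out) <- "pca_report"
    return(out)
  }
  p <- stats::prcomp(sv, center = FALSE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x
  out <- list(variance_explained = ve, scores = scores, degenerate = FALSE,
              design = design)
  class(out) <- "pca_report"
  out
}

#' @export
print.pca_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<pca_report> degenerate (no sample variance)\n")
  } else {
    k <- min(3L, length(x$variance_explained))
    cat("<pca_report> variance explained:",
        paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_explained[seq_len(k)]),
              collapse = ", "), "\n")
  }
  invisible(x)
}
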