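#' One-way ANOVA from printed group summaries
#'
#' Recomputes the one-way ANOVA F and P from per-group mean, SD and n alone,
#' the form in which carcass-trait tables are printed (mean +/- SD, n per
#' group). `SS_between = sum n_i (mean_i - grand_mean)^2`,
#' `SS_within = sum (n_i - 1) SD_i^2`.
#'
#' @param summaries data.frame with columns `group`, `mean`, `sd`, `n`
#'   (n >= 2, sd >= 0), one row per group.
#' @return an object of class `anova_result`: F statistic, `df_between`,
#'   `df_within`, `p`, and `infinite_f` flag (TRUE when SS_within = 0 with
#'   unequal means; P is reported as 0).
#' @export
anova_from_summaries <- function(summaries) {
  summaries <- as.data.frame(summaries)
  req <- c("group", "mean", "sd", "n")
  if (!all(req %in% names(summaries))) {
    stop("'summaries' needs columns group, mean, sd, n", call. = FALSE)
  }
  if (nrow(summaries) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (anyDuplicated(summaries$group)) stop("duplicate group labels", call. = FALSE)
  if (any(summaries$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(summaries$sd < 0)) stop("SDs must be non-negative", call. = FALSE)
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  grand <- sum(n * m) / sum(n)
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * s^2)
  df_between <- nrow(summaries) - 1L
  df_within <- sum(n - 1L)
  if (ss_between <= .Machine$double.eps * max(1, sum(n * m^2))) {
    out <- list(f = 0, df_between = df_between, df_within = df_within, p = 1,
                infinite_f = FALSE, ms_within = ss_within / df_within,
                summaries = summaries)
  } else if (ss_within == 0) {
    out <- list(f = Inf, df_between = df_between, df_within = df_within, p = 0,
                infinite_f = TRUE, ms_within = 0, summaries = summaries)
  } else {
    f <- (ss_between / df_between) / (ss_within / df_within)
    out <- list(f = f, df_between = df_between, df_within = df_within,
                p = stats::pf(f, df_between, df_within, lower.tail = FALSE),
                infinite_f = FALSE, ms_within = ss_within / df_within,
                summaries = summaries)
  }
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %s, P = %s%s\n",
              x$df_between, x$df_within,
              if (x$infinite_f) "Inf" else sprintf("%.4g", x$f),
              sprintf("%.4g", x$p),
              if (x$infinite_f) " (zero within-group variance)" else ""))
  invisible(x)
}

as_group_list <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("group", "value") %in% names(data))) {
      stop("'data' must be a named list of vectors or a data.frame(group, value)",
           call. = FALSE)
    }
    data <- split(data$value, data$group)
  }
  if (!is.list(data) || is.null(names(data))) {
    stop("'data' must be a named list of numeric vectors", call. = FALSE)
  }
  data
}

#' One-way ANOVA from raw per-group data
#'
#' Classic decomposition computed directly from the observations; agrees with
#' [anova_from_summaries()] applied to the empirical moments.
#'
#' @param data named list of numeric vectors (one per group), or a
#'   data.frame with columns `group` and `value`.
#' @return an `anova_result` (see [anova_from_summaries()]).
#' @export
anova_from_raw <- function(data) {
  data <- as_group_list(data)
  if (length(data) < 2) stop("at least 2 groups are required", call. = FALSE)
  n <- lengths(data)
  if (any(n < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(data)[n < 2], collapse = ", "), call. = FALSE)
  }
  all_v <- unlist(data, use.names = FALSE)
  grand <- mean(all_v)
  means <- vapply(data, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(data, function(v) sum((v - mean(v))^2), numeric(1)))
  df_between <- length(data) - 1L
  df_within <- sum(n) - length(data)
  if (ss_between <= .Machine$double.eps * max(1, sum(all_v^2))) {
    out <- list(f = 0, df_between = df_between, df_within = df_within, p = 1,
                infinite_f = FALSE, ms_within = ss_within / df_within,
                summaries = NULL)
  } else if (ss_within == 0) {
    out <- list(f = Inf, df_between = df_between, df_within = df_within, p = 0,
                infinite_f = TRUE, ms_within = 0, summaries = NULL)
  } else {
    f <- (ss_between / df_between) / (ss_within / df_within)
    out <- list(f = f, df_between = df_between, df_within = df_within,
                p = stats::pf(f, df_between, df_within, lower.tail = FALSE),
                infinite_f = FALSE, ms_within = ss_within / df_within,
                summaries = NULL)
  }
  out$summaries <- data.frame(group = names(data), mean = means,
                              sd = vapply(data, stats::sd, numeric(1)),
                              n = as.integer(n), stringsAsFactors = FALSE,
                              row.names = NULL)
  class(out) <- "anova_result"
  out
}

#' Duncan's multiple range test with letter display
#'
#' Stepwise post-hoc comparison of group means. Groups are sorted by mean;
#' a range spanning `p` ordered means is significant when it exceeds the
#' critical range `q'(p, df_within, alpha) * sqrt(MS_within / n_h)`, where
#' `q'` is the studentized-range quantile at Duncan's protection level
#' `(1 - alpha)^(p - 1)` and `n_h` is the harmonic mean of the group sizes.
#' A pair inside a non-significant enclosing range is never declared
#' different (the standard containment rule); groups are then lettered by
#' line connection — groups sharing a letter are not significantly different.
#'
#' @param data named list of numeric vectors or data.frame(group, value).
#' @param alpha significance level (default 0.05).
#' @return an object of class `duncan_letters`: `letters` (named character,
#'   group -> letter string), `means`, `comparisons` (pairwise decisions with
#'   critical ranges), `ms_within`, `alpha`.
#' @export
duncan_letters <- function(data, alpha = 0.05) {
  data <- as_group_list(data)
  an <- anova_from_raw(data)
  if (an$ms_within == 0) {
    stop("degenerate input: zero within-group variance", call. = FALSE)
  }
  k <- length(data)
  means <- sort(vapply(data, mean, numeric(1)), decreasing = TRUE)
  glab <- names(means)
  n_h <- k / sum(1 / lengths(data))
  se <- sqrt(an$ms_within / n_h)
  crit <- c(NA_real_,
            vapply(2:k, function(p) {
              stats::qtukey((1 - alpha)^(p - 1), p, an$df_within) * se
            }, numeric(1)))

  sep <- matrix(FALSE, k, k)            # TRUE = significantly different
  nonsig <- matrix(FALSE, k, k)         # recorded non-significant ranges
  comparisons <- NULL
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      contained <- FALSE
      if (span < k) {
        for (a in seq_len(i)) for (b in j:k) {
          if ((a < i || b > j) && nonsig[a, b]) { contained <- TRUE; break }
        }
      }
      diff <- means[i] - means[j]
      sig <- !contained && diff > crit[span]
      sep[i, j] <- sep[j, i] <- sig
      if (!sig) nonsig[i, j] <- TRUE
      comparisons <- rbind(comparisons,
                           data.frame(group_hi = glab[i], group_lo = glab[j],
                                      span = span, difference = diff,
                                      critical_range = crit[span],
                                      contained = contained, significant = sig,
                                      stringsAsFactors = FALSE))
    }
  }
  # line connection: maximal runs [i, r_i] of mutually non-separated groups
  runs <- list()
  for (i in seq_len(k)) {
    r <- i
    while (r < k && !sep[i, r + 1]) r <- r + 1
    runs[[i]] <- c(i, r)
  }
  keep <- vapply(seq_along(runs), function(ii) {
    !any(vapply(seq_along(runs), function(jj) {
      jj != ii && runs[[jj]][1] <= runs[[ii]][1] && runs[[ii]][2] <= runs[[jj]][2]
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_by_group <- stats::setNames(rep("", k), glab)
  for (li in seq_along(runs)) {
    rng <- runs[[li]][1]:runs[[li]][2]
    letters_by_group[rng] <- paste0(letters_by_group[rng], letters[li])
  }
  out <- list(letters = letters_by_group, means = means,
              comparisons = comparisons, ms_within = an$ms_within,
              df_within = an$df_within, n_h = n_h, alpha = alpha)
  class(out) <- "duncan_letters"
  out
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat(sprintf("<duncan_letters> alpha = %g\n", x$alpha))
  for (g in names(x$means)) {
    cat(sprintf("  %-6s %10.4g  %s\n", g, x$means[[g]], x$letters[[g]]))
  }
  invisible(x)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' dCt of the calibrator group; relative expression is `2^-ddCt`, so the
#' calibrator group's geometric mean is 1.
#'
#' @param records data.frame with columns `sample`, `group`, `target_ct`,
#'   `reference_ct` (finite, positive Ct values; reference is typically the
#'   beta-actin assay).
#' @param calibrator_group group label used as calibrator (e.g. `"NC"`).
#' @return an object of class `ddct_result`: `samples` (per-sample dCt, ddCt,
#'   relative expression) and `groups` (per-group n, mean, SD, geometric mean
#'   of relative expression).
#' @export
ddct <- function(records, calibrator_group) {
  req <- c("sample", "group", "target_ct", "reference_ct")
  if (!all(req %in% names(records))) {
    stop("'records' needs columns sample, group, target_ct, reference_ct",
         call. = FALSE)
  }
  ct <- c(records$target_ct, records$reference_ct)
  if (!all(is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  if (!calibrator_group %in% records$group) {
    stop("calibrator group '", calibrator_group, "' absent from records",
         call. = FALSE)
  }
  dct <- records$target_ct - records$reference_ct
  cal_mean <- mean(dct[records$group == calibrator_group])
  ddct_v <- dct - cal_mean
  rel <- 2^(-ddct_v)
  samples <- data.frame(sample = records$sample, group = records$group,
                        dct = dct, ddct = ddct_v, relative_expression = rel,
                        stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_relative = mean(d$relative_expression),
               sd_relative = if (nrow(d) > 1) stats::sd(d$relative_expression) else NA_real_,
               geomean_relative = exp(mean(log(d$relative_expression))),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  out <- list(samples = samples, groups = groups, calibrator = calibrator_group)
  class(out) <- "ddct_result"
  out
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> calibrator = %s\n", x$calibrator))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Simulate raw trait data matching group summaries
#'
#' Draws normal data per group; with `exact = TRUE` (default) each group's
#' sample mean and SD are rescaled to equal the target summaries exactly, so
#' downstream statistics that depend only on the group moments (one-way
#' ANOVA, Duncan's ranges) reproduce the summary-level analysis while the
#' individual values vary between draws.
#'
#' @param summaries data.frame with columns group, mean, sd, n.
#' @param exact logical; match moments exactly (TRUE) or only in expectation.
#' @param seed optional integer seed.
#' @return named list of numeric vectors, one per group.
#' @export
simulate_trait_data <- function(summaries, exact = TRUE, seed = NULL) {
  summaries <- as.data.frame(summaries)
  gen <- function() {
    out <- lapply(seq_len(nrow(summaries)), function(i) {
      z <- stats::rnorm(summaries$n[i])
      if (exact) z <- (z - mean(z)) / stats::sd(z)
      summaries$mean[i] + summaries$sd[i] * z
    })
    stats::setNames(out, summaries$group)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate qPCR Ct records with planted fold changes
#'
#' Generates per-sample target and reference Ct values for a set of groups,
#' with group-level log2 fold changes relative to the calibrator encoded as
#' shifts in dCt (a 2-fold up-regulation is `log2_fc = 1`, i.e. ddCt = -1).
#'
#' @param log2_fc named numeric: group -> log2 fold change vs calibrator.
#' @param n_per_group samples per group.
#' @param base_dct mean dCt of the calibrator condition.
#' @param reference_ct mean reference-gene Ct.
#' @param ct_sd technical SD of each Ct measurement.
#' @param seed integer seed.
#' @return data.frame of qPCR records suitable for [ddct()].
#' @export
simulate_qpcr_records <- function(log2_fc = c(NC = 0, HS = 1, PF = 0),
                                  n_per_group = 6, base_dct = 3,
                                  reference_ct = 15, ct_sd = 0.2, seed = 1L) {
  with_seed(seed, {
    recs <- lapply(names(log2_fc), function(g) {
      ref <- stats::rnorm(n_per_group, reference_ct, ct_sd)
      tgt <- ref + base_dct - log2_fc[[g]] + stats::rnorm(n_per_group, 0, ct_sd)
      data.frame(sample = paste0(g, "_", seq_len(n_per_group)), group = g,
                 target_ct = tgt, reference_ct = ref, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
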