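# shared fixtures built in code

# tiny expression matrix with controlled totals
tiny_expr <- function(values, class = "lncRNA", lengths = NULL) {
  expression_matrix(values, class, lengths = lengths)
}

# fabricate a de_result with prescribed DE calls (for venn_filter unit tests)
fake_de <- function(universe, up = character(0), down = character(0),
                    contrast = "HS_vs_NC") {
  tab <- data.frame(
    feature = universe, log2fc = 0, pvalue = 1, padj = 1,
    de = universe %in% c(up, down),
    direction = ifelse(universe %in% up, "up",
                       ifelse(universe %in% down, "down", "ns")),
    stringsAsFactors = FALSE)
  structure(list(table = tab, contrast = contrast,
                 groups = strsplit(contrast, "_vs_")[[1]],
                 alpha = 0.05, fc_threshold = 1.5, adjusted = FALSE,
                 feature_class = "lncRNA"),
            class = "de_result")
}

# independent inclusive upper-tail hypergeometric oracle by direct enumeration
hyper_upper_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# do two Duncan letter strings share a letter?
letters_shared <- function(a, b) {
  length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
}

# printed carcass-trait summaries used across validation tests
table2_summaries <- function(trait = c("body_weight", "breast_muscle",
                                       "thigh_muscle", "half_eviscerated")) {
  trait <- match.arg(trait)
  rows <- list(
    body_weight = data.frame(group = c("NC", "HS", "PF"),
                             mean = c(2637.5, 2391.67, 2455.83),
                             sd = c(201.32, 233.16, 184.23), n = 12),
    breast_muscle = data.frame(group = c("NC", "HS", "PF"),
                               mean = c(26.61, 24.87, 26.25),
                               sd = c(1.45, 1.27, 2.01), n = 12),
    thigh_muscle = data.frame(group = c("NC", "HS", "PF"),
                              mean = c(18.10, 18.61, 17.84),
                              sd = c(0.81, 0.44, 1.35), n = 12),
    half_eviscerated = data.frame(group = c("NC", "HS", "PF"),
                                  mean = c(90.73, 91.26, 91.44),
                                  sd = c(1.36, 0.75, 0.76), n = 12))
  rows[[trait]]
}
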