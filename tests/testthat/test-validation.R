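test_that("summary-level ANOVA handles equal means and degenerate variance", {
  eq <- data.frame(group = c("a", "b", "c"), mean = 5, sd = 1, n = 6)
  r <- anova_from_summaries(eq)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df_between, 2L)
  expect_equal(r$df_within, 15L)

  degen <- data.frame(group = c("a", "b"), mean = c(1, 2), sd = 0, n = 4)
  rd <- anova_from_summaries(degen)
  expect_true(rd$infinite_f)
  expect_equal(rd$p, 0)

  expect_error(anova_from_summaries(eq[1, ]), "2 groups")
  expect_error(anova_from_summaries(transform(eq, n = 1)), "n >= 2")
})

test_that("raw-data ANOVA matches both the summary route and lm/aov", {
  set.seed(5)
  for (rep in 1:5) {
    data <- list(NC = rnorm(12, 10, 2), HS = rnorm(12, 9, 2), PF = rnorm(10, 9.5, 2))
    raw <- anova_from_raw(data)
    # round trip through empirical moments
    summ <- data.frame(group = names(data),
                       mean = sapply(data, mean),
                       sd = sapply(data, sd),
                       n = lengths(data))
    via_summ <- anova_from_summaries(summ)
    expect_equal(raw$f, via_summ$f, tolerance = 1e-10)
    expect_equal(raw$p, via_summ$p, tolerance = 1e-10)
    # independent oracle: stats::lm anova table
    df <- data.frame(value = unlist(data),
                     group = rep(names(data), lengths(data)))
    tab <- anova(lm(value ~ group, df))
    expect_equal(raw$f, tab$`F value`[1], tolerance = 1e-10)
    expect_equal(raw$p, tab$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # permuting within groups leaves F unchanged
  d <- list(a = c(1, 5, 3, 2), b = c(4, 2, 2, 8))
  dperm <- lapply(d, sample)
  expect_equal(anova_from_raw(d)$f, anova_from_raw(dperm)$f, tolerance = 1e-12)
  expect_equal(anova_from_raw(list(a = 1:3, b = 1:3))$f, 0)
  expect_error(anova_from_raw(list(a = 1:3, b = 2)), "fewer than 2")
})

test_that("Duncan letters separate and group as the critical ranges dictate", {
  # identical group distributions share one letter
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_identical(unname(duncan_letters(same)$letters), rep("a", 3))

  # three well-separated groups get three distinct letters; verify against a
  # direct pairwise computation of Duncan critical ranges
  set.seed(1)
  far <- list(lo = rnorm(12, 0, 0.1), mid = rnorm(12, 10, 0.1), hi = rnorm(12, 20, 0.1))
  dl <- duncan_letters(far)
  expect_length(unique(dl$letters), 3L)
  an <- anova_from_raw(far)
  se <- sqrt(an$ms_within / 12)
  means <- sort(sapply(far, mean), decreasing = TRUE)
  for (p in 2:3) {
    crit <- qtukey((1 - 0.05)^(p - 1), p, an$df_within) * se
    for (i in 1:(3 - p + 1)) expect_gt(means[i] - means[i + p - 1], crit)
  }

  expect_error(duncan_letters(list(a = c(1, 1, 1), b = c(2, 2, 2))), "degenerate")
})

test_that("Duncan reproduces the printed carcass letter patterns", {
  # body weight: NC separated, HS and PF sharing a letter (a/b/b)
  bw <- simulate_trait_data(table2_summaries("body_weight"), exact = TRUE, seed = 1)
  l <- duncan_letters(bw)$letters
  expect_false(letters_shared(l[["NC"]], l[["HS"]]))
  expect_false(letters_shared(l[["NC"]], l[["PF"]]))
  expect_true(letters_shared(l[["HS"]], l[["PF"]]))
  # breast muscle yield: HS separated from NC and PF (a/b/a)
  bm <- simulate_trait_data(table2_summaries("breast_muscle"), exact = TRUE, seed = 2)
  lb <- duncan_letters(bm)$letters
  expect_false(letters_shared(lb[["HS"]], lb[["NC"]]))
  expect_false(letters_shared(lb[["HS"]], lb[["PF"]]))
  expect_true(letters_shared(lb[["NC"]], lb[["PF"]]))
})

test_that("exact-moment trait simulation matches its targets", {
  summ <- table2_summaries("body_weight")
  d <- simulate_trait_data(summ, exact = TRUE, seed = 9)
  expect_equal(sapply(d, mean), setNames(summ$mean, summ$group), tolerance = 1e-12)
  expect_equal(sapply(d, sd), setNames(summ$sd, summ$group), tolerance = 1e-12)
  # non-exact draws differ between seeds but keep the moments in expectation
  d2 <- simulate_trait_data(summ, exact = FALSE, seed = 10)
  expect_false(isTRUE(all.equal(sapply(d2, mean), setNames(summ$mean, summ$group))))
})

test_that("ddct quantification follows the 2^-ddCt algebra", {
  rec <- data.frame(sample = paste0("s", 1:4),
                    group = c("NC", "NC", "HS", "HS"),
                    target_ct = c(17, 17, 19, 19),
                    reference_ct = c(15, 15, 15, 15))
  r <- ddct(rec, "NC")
  # calibrator samples at the calibrator mean dCt -> relative expression 1
  expect_equal(r$samples$relative_expression[1:2], c(1, 1))
  # treatment dCt 4 vs calibrator mean 2 -> 2^-2
  expect_equal(r$samples$relative_expression[3:4], c(0.25, 0.25))
  expect_equal(r$groups$geomean_relative[r$groups$group == "NC"], 1,
               tolerance = 1e-9)

  # invariant to adding a constant to both Ct values of a sample
  rec2 <- rec; rec2$target_ct <- rec2$target_ct + 3; rec2$reference_ct <- rec2$reference_ct + 3
  expect_equal(ddct(rec2, "NC")$samples$relative_expression,
               r$samples$relative_expression, tolerance = 1e-12)
  expect_error(ddct(rec, "PF"), "PF")
  bad <- rec; bad$target_ct[1] <- -1
  expect_error(ddct(bad, "NC"), "finite")

  # planted 2-fold up-regulation recovered from simulated Ct records
  sim <- simulate_qpcr_records(log2_fc = c(NC = 0, HS = 1, PF = 0),
                               n_per_group = 50, ct_sd = 0.15, seed = 8)
  rs <- ddct(sim, "NC")
  hs_mean <- rs$groups$mean_relative[rs$groups$group == "HS"]
  expect_equal(hs_mean, 2, tolerance = 0.15)
})
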