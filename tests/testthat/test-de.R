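test_that("size factors track depth scaling", {
  set.seed(1)
  v <- matrix(rpois(200 * 6, 100) + 1, nrow = 200,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:6)))
  sf <- size_factors(v)
  v2 <- v; v2[, 2] <- v[, 2] * 3
  sf2 <- size_factors(v2)
  # size factors are relative; the scaled sample's factor triples against any
  # untouched reference sample
  expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 3, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(size_factors(matrix(0, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "geometric mean")
})

test_that("degenerate features and input validation behave as contracted", {
  set.seed(2)
  n <- 4
  cnt <- matrix(rpois(20 * 3 * n, 80), nrow = 20)
  rownames(cnt) <- paste0("f", 1:20)
  grp <- rep(c("NC", "HS", "PF"), each = n)
  colnames(cnt) <- paste0(grp, "_", rep(1:n, 3))
  cnt["f1", ] <- rep(c(30, 60, 45), each = n)  # identical within all groups
  cnt["f2", ] <- 0                             # all-zero feature
  x <- tiny_expr(cnt)
  d <- sample_design(colnames(cnt), grp)
  de <- differential_expression(x, d, c("HS", "NC"))
  t1 <- de$table[de$table$feature == "f2", ]
  expect_equal(t1$pvalue, 1)
  expect_equal(t1$log2fc, 0)
  expect_identical(t1$direction, "ns")

  expect_error(differential_expression(x, d, c("HS", "XX")), "XX")
  expect_error(differential_expression(x, d, c("HS", "NC"), alpha = 1.2), "alpha")
  # identical values in both contrast groups -> log2FC exactly 0
  cnt2 <- cnt; cnt2["f3", grp != "PF"] <- rep(c(50, 50), each = n)
  # make normalization symmetric: equal library scale
  de2 <- differential_expression(tiny_expr(cnt2), d, c("HS", "NC"))
  f3 <- de2$table[de2$table$feature == "f3", ]
  expect_false(f3$de)
})

test_that("contrast reversal negates log2FC and preserves P", {
  s <- simulate_chs_dataset(sim_config(n_lncRNA = 150, seed = 9))
  a <- differential_expression(s$lncRNA, s$design, c("HS", "NC"))
  b <- differential_expression(s$lncRNA, s$design, c("NC", "HS"))
  expect_equal(a$table$log2fc, -b$table$log2fc, tolerance = 1e-8)
  expect_equal(a$table$pvalue, b$table$pvalue, tolerance = 1e-8)
})

test_that("planted heat effects are detected with high power", {
  hits <- 0; total <- 0
  for (sd in 1:50) {
    s <- simulate_chs_dataset(sim_config(seed = 100 + sd))
    de <- differential_expression(s$lncRNA, s$design, c("HS", "NC"))
    tab <- de$table[match(s$truth$heat_specific$feature, de$table$feature), ]
    ok <- tab$de & tab$direction == s$truth$heat_specific$direction
    hits <- hits + sum(ok); total <- total + nrow(tab)
  }
  expect_gte(hits / total, 0.8)
})

test_that("log2 fold changes agree with an independent NB engine", {
  skip_if_not_installed("DESeq2")
  s <- simulate_chs_dataset(sim_config(n_lncRNA = 200, seed = 33))
  keep <- s$design$group %in% c("HS", "NC")
  cnt <- s$lncRNA$values[, s$design$sample[keep]]
  de <- differential_expression(s$lncRNA, s$design, c("HS", "NC"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, S4Vectors::DataFrame(condition = factor(s$design$group[keep],
                                                   levels = c("NC", "HS"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "HS", "NC"))
  })
  lfc_ref <- res$log2FoldChange[match(de$table$feature, rownames(res))]
  ok <- is.finite(lfc_ref)
  expect_gt(stats::cor(de$table$log2fc[ok], lfc_ref[ok]), 0.9)
  # planted features called in the same direction by both engines
  planted <- s$truth$heat_specific$feature
  i <- match(planted, de$table$feature)
  expect_gt(mean(sign(de$table$log2fc[i]) ==
                   sign(lfc_ref[match(planted, de$table$feature)])), 0.9)
})

test_that("venn screen implements the pair-fed set algebra", {
  u <- paste0("l", 1:6)
  hs_nc <- fake_de(u, up = c("l1", "l2", "l3"), contrast = "HS_vs_NC")
  hs_pf <- fake_de(u, up = c("l2", "l3", "l4"), contrast = "HS_vs_PF")
  nc_pf <- fake_de(u, up = "l3", contrast = "NC_vs_PF")
  out <- venn_filter(hs_nc, hs_pf, nc_pf)
  expect_identical(out$members$feature, "l2")
  expect_identical(out$members$direction, "up")
  expect_equal(out$n_up, 1L)

  # empty HS-vs-NC DE set -> empty output
  empty <- venn_filter(fake_de(u), hs_pf, nc_pf)
  expect_equal(nrow(empty$members), 0L)

  # direction consistency required: l2 up in one, down in the other
  flip <- venn_filter(hs_nc, fake_de(u, down = "l2", contrast = "HS_vs_PF"),
                      fake_de(u, contrast = "NC_vs_PF"))
  expect_false("l2" %in% flip$members$feature)

  # dropping the NC-vs-PF exclusion restores the pure intersection
  keep3 <- venn_filter(hs_nc, hs_pf, nc_pf, exclude_nc_pf = FALSE)
  expect_setequal(keep3$members$feature, c("l2", "l3"))

  # monotone: shrinking the NC-vs-PF DE set can only grow the output
  for (sub in list("l3", character(0))) {
    o <- venn_filter(hs_nc, hs_pf, fake_de(u, up = sub, contrast = "NC_vs_PF"))
    expect_true(all(out$members$feature %in% o$members$feature))
  }

  expect_error(venn_filter(hs_nc, hs_pf, fake_de(paste0("l", 2:7))), "l1")
})
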