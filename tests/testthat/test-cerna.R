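test_that("spearman and pearson edges match direct formulas", {
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$value, -1)
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30))$value, 1)
  expect_equal(pearson(c(1, 2, 3), 2 * c(1, 2, 3) + 1)$value, 1)
  expect_equal(pearson(c(1, 2, 3), -c(1, 2, 3))$value, -1)

  # tied data against an explicit mid-rank + covariance oracle
  x <- c(1, 1, 2, 3); y <- c(4, 3, 2, 1)
  midrank <- function(v) {
    sapply(v, function(a) mean(which(sort(v) == a)))
  }
  rx <- midrank(x); ry <- midrank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(x, y)$value, oracle, tolerance = 1e-12)

  set.seed(13)
  a <- rnorm(18); b <- rnorm(18)
  oracle_p <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b)$value, oracle_p, tolerance = 1e-12)

  # undefined on zero variance; excluded rather than propagated
  e <- pearson(rep(2, 5), rnorm(5))
  expect_false(e$ok)
  expect_true(is.na(e$value))
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(spearman(1:4, 1:3), "equal length")
})

test_that("sponge test equals exact combinatorial enumeration", {
  u <- paste0("m", 1:10)
  expect_equal(sponge_test(u[1:4], u[5:9], u), 1)             # k = 0
  expect_equal(sponge_test(u[1:4], u[c(1, 2, 3, 9, 10)], u), 66 / 252,
               tolerance = 1e-12)
  expect_equal(sponge_test(u, u, u), 1)                        # forced overlap
  expect_error(sponge_test(c("m1", "zz"), u[1:2], u), "zz")

  # full sweep N <= 12 against the enumeration oracle
  for (N in 1:12) {
    un <- paste0("m", 1:N)
    for (K in 0:N) for (n in 0:N) {
      for (k in max(0, K + n - N):min(K, n)) {
        lnc <- un[seq_len(K)]
        mrna <- c(un[seq_len(k)], setdiff(un, lnc)[seq_len(n - k)])
        expect_equal(sponge_test(lnc, mrna, un),
                     hyper_upper_oracle(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("triplet assembly applies strict thresholds and recovers plants", {
  s <- simulate_chs_dataset(sim_config(seed = 2))
  pairs <- generate_target_pairs(s, n_decoys = 100, seed = 2)
  scr <- run_chs_screen(s$lncRNA, s$design, s$miRNA, s$mRNA, pairs)
  expect_gt(length(scr$triplets$triplets), 0)

  # every emitted triplet re-validates from the matrices (round trip)
  ll <- heatCeRNA:::log_expression(s$lncRNA)
  ml <- heatCeRNA:::log_expression(s$miRNA)
  rl <- heatCeRNA:::log_expression(s$mRNA)
  th <- scr$triplets$thresholds
  for (t in scr$triplets$triplets) {
    expect_gt(cor(ll[t$lncRNA, ], rl[t$mRNA, ]), th["pcc"])
    expect_equal(unname(t$pcc), cor(ll[t$lncRNA, ], rl[t$mRNA, ]), tolerance = 1e-12)
    for (mi in t$mirnas) {
      expect_lt(cor(ll[t$lncRNA, ], ml[mi, ], method = "spearman"), th["scc"])
      expect_lt(cor(rl[t$mRNA, ], ml[mi, ], method = "spearman"), th["scc"])
    }
    expect_lt(t$sponge_p, th["alpha"])
  }

  # invariant to target-pair row order
  shuf <- pairs[sample(nrow(pairs)), ]
  t2 <- build_triplets(s$lncRNA, s$miRNA, s$mRNA, shuf, scr$heat_set)
  expect_equal(as.data.frame(scr$triplets), as.data.frame(t2))

  # strictness at the PCC boundary: a triplet is dropped when the threshold
  # equals its observed correlation (strict >), kept just below it
  t0 <- scr$triplets$triplets[[1]]
  pcc0 <- t0$pcc
  at <- build_triplets(s$lncRNA, s$miRNA, s$mRNA, pairs, scr$heat_set,
                       pcc_threshold = pcc0)
  below <- build_triplets(s$lncRNA, s$miRNA, s$mRNA, pairs, scr$heat_set,
                          pcc_threshold = pcc0 - 1e-9)
  key <- function(tr) vapply(tr$triplets, function(t) paste(t$lncRNA, t$mRNA), "")
  expect_false(paste(t0$lncRNA, t0$mRNA) %in% key(at))
  expect_true(paste(t0$lncRNA, t0$mRNA) %in% key(below))

  # empty pair list -> no triplets, with a warning
  expect_warning(
    t3 <- build_triplets(s$lncRNA, s$miRNA, s$mRNA, pairs[0, ], scr$heat_set),
    "empty")
  expect_length(t3$triplets, 0)
})

test_that("network assembly counts nodes, edges and degrees correctly", {
  one <- list(list(lncRNA = "l1", mRNA = "g1", mirnas = "m1",
                   pcc = 0.95, scc_lnc = c(m1 = -0.8), scc_mrna = c(m1 = -0.8),
                   sponge_p = 0.01))
  net1 <- assemble_network(one)
  expect_equal(nrow(net1$nodes), 3L)
  expect_equal(nrow(net1$edges), 2L)
  expect_equal(unname(net1$edge_counts["lncRNA-miRNA"]), 1L, ignore_attr = TRUE)

  two <- c(one, list(list(lncRNA = "l2", mRNA = "g2", mirnas = "m1",
                          pcc = 0.95, scc_lnc = c(m1 = -0.8),
                          scc_mrna = c(m1 = -0.8), sponge_p = 0.01)))
  net2 <- assemble_network(two)
  expect_equal(net2$nodes$degree[net2$nodes$id == "m1"], 4L)
  # shared miRNA: edges deduplicate below the per-triplet bound
  s <- simulate_chs_dataset(sim_config(seed = 6))
  scr <- run_chs_screen(s$lncRNA, s$design, s$miRNA, s$mRNA,
                        generate_target_pairs(s, seed = 6))
  bound <- sum(vapply(scr$triplets$triplets,
                      function(t) 1 + length(t$mirnas), numeric(1)))
  expect_lte(nrow(scr$network$edges), bound)
  # degrees equal an independent recount over the edge list
  e <- scr$network$edges
  recount <- table(c(e$source, e$target))
  expect_equal(scr$network$nodes$degree,
               as.integer(recount[scr$network$nodes$id]))
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  star <- lapply(paste0("g", 1:5), function(g) {
    list(lncRNA = "l1", mRNA = g, mirnas = "hub_mi",
         pcc = 0.95, scc_lnc = c(hub_mi = -0.8), scc_mrna = c(hub_mi = -0.8),
         sponge_p = 0.01)
  })
  net <- assemble_network(star)
  hubs <- rank_hubs(net, 2)
  expect_identical(hubs$id[1], "hub_mi")
  expect_equal(hubs$degree[1], 6L)   # 1 deduplicated lncRNA leg + 5 mRNA legs
  # ties broken lexicographically (b_l and c_g both degree 1)
  tied <- assemble_network(list(list(lncRNA = "b_l", mRNA = "c_g", mirnas = "a_m",
                                     pcc = 0.95, scc_lnc = c(a_m = -0.8),
                                     scc_mrna = c(a_m = -0.8), sponge_p = 0.01)))
  h <- rank_hubs(tied, 3)
  expect_identical(h$id, c("a_m", "b_l", "c_g"))
  expect_warning(rank_hubs(assemble_network(list()), 3), "empty")
})
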