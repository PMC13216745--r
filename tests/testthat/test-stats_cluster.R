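test_that("Kruskal-Wallis matches the hand-computed rank formula", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- kruskal_wallis(same)
  expect_equal(r$H, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # ranks 1..9 without ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  r2 <- kruskal_wallis(list(a = c(1, 2, 3), b = c(7, 8, 9), c = c(4, 5, 6)))
  expect_equal(r2$H, 7.2)
  expect_equal(r2$df, 2)

  # two-group case agrees in direction with the rank-sum test
  g <- list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13))
  kw <- kruskal_wallis(g)
  ws <- wilcox.test(g$a, g$b)
  expect_lt(kw$p, 0.05)
  expect_lt(ws$p.value, 0.05)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("Dunn's test reproduces the pooled-rank formula with BH", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  d <- dunn_bh(groups)
  # independent arithmetic: pooled ranks and tie-corrected variance
  x <- unlist(groups)
  g <- rep(names(groups), each = 3)
  rk <- rank(x)
  N <- length(x)
  ties <- table(x)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (mean(rk[g == "a"]) - mean(rk[g == "b"])) / sqrt(v0 * (2 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab)
  raw <- 2 * pnorm(-abs(d$z))
  expect_equal(d$p, raw)
  expect_equal(d$p_adj, p.adjust(raw, "BH"))
  # the shifted group has the smallest adjusted p-values
  pc <- d$p_adj[d$group2 == "c" | d$group1 == "c"]
  expect_true(all(pc < d$p_adj[d$group1 == "a" & d$group2 == "b"]))
  # invariance under relabeling
  d2 <- dunn_bh(rev(groups))
  expect_setequal(round(d2$p_adj, 12), round(d$p_adj, 12))

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_true(all(dunn_bh(same)$p_adj > 0.99))
})

test_that("BH adjustment equals hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(.005, .011, .02, .04)),
               c(0.02, 0.022, 4 * .02 / 3, 0.04))
  expect_equal(bh_adjust(c(.01, .02, .03)), c(.03, .03, .03))
  # monotone in the input ranks
  p <- c(.001, .04, .013, .8, .2)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("loop sharing classifies against brute-force anchor matching", {
  mk <- function(c1, c2) data.frame(
    chrom1 = "chrA", start1 = c1 - 1000, end1 = c1 + 1000,
    chrom2 = "chrA", start2 = c2 - 1000, end2 = c2 + 1000)
  ref <- mk(c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5), c(1.5e5, 2.5e5, 3.5e5, 4.5e5, 5.5e5, 6.5e5))
  # designed overlaps: loops 1-3 in both, 4-5 only in B, 6 nowhere
  condA <- mk(c(1e5, 2e5, 3e5) + 500, c(1.5e5, 2.5e5, 3.5e5) - 500)
  condB <- mk(c(1e5, 2e5, 3e5, 4e5, 5e5), c(1.5e5, 2.5e5, 3.5e5, 4.5e5, 5.5e5))
  sh <- loop_sharing(list(ref = ref, A = condA, B = condB), tolerance = 2000)
  expect_equal(unname(sh$counts["all"]), 3)
  expect_equal(unname(sh$counts["only_B"]), 2)
  expect_equal(unname(sh$counts["specific"]), 1)
  expect_equal(sum(sh$counts), nrow(ref))

  ident <- loop_sharing(list(x = ref, y = ref), tolerance = 0)
  expect_true(all(ident$class == "all"))
  none <- loop_sharing(list(x = ref, y = ref[0, ]), tolerance = 1000)
  expect_true(all(none$class == "specific"))
})

test_that("signal matrices integrate bedGraph steps exactly", {
  track <- data.frame(chrom = "chrA", start = c(1, 1001, 2001),
                      end = c(1000, 2000, 40000),
                      value = c(2, 2, 2))
  feats <- data.frame(chrom = "chrA", summit = c(20000, 30000))
  feats$start <- feats$summit - 10; feats$end <- feats$summit + 10
  M <- extract_signal_matrix(track, feats, flank = 5000, n_bins = 10)
  expect_true(all(M == 2))

  # step function crossing the centre: left/right halves differ
  step <- data.frame(chrom = "chrA", start = c(1, 20001),
                     end = c(20000, 40000), value = c(1, 5))
  M2 <- extract_signal_matrix(step, feats[1, ], flank = 4000, n_bins = 8)
  expect_equal(as.numeric(M2[1, 1:4]), rep(1, 4))
  expect_equal(as.numeric(M2[1, 6:8]), rep(5, 3))
  # hand binning of the straddling bin [19000, 20000]: 1000 bp at 1,
  # 0 bp at 5 -> exactly 1... and [20000,21000): 1 bp at 1 (position 20000)
  expect_equal(as.numeric(M2[1, 5]), (1 * 1 + 999 * 5) / 1000)

  # feature at the chromosome start: leading bins masked
  edge <- data.frame(chrom = "chrA", summit = 500, start = 490, end = 510)
  M3 <- extract_signal_matrix(step, edge, flank = 2000, n_bins = 4,
                              chromsizes = chrom_sizes(c(chrA = 4e4)))
  expect_true(any(is.na(M3)))
  expect_false(all(is.na(M3)))
})

test_that("k-means clustering is deterministic and handles degenerate input", {
  set.seed(1)
  # two patterned classes (high-then-low vs low-then-high) that survive
  # per-row z-scoring
  M <- rbind(cbind(matrix(rnorm(25, 5), 5), matrix(rnorm(25, 0), 5)),
             cbind(matrix(rnorm(25, 0), 5), matrix(rnorm(25, 5), 5)))
  km <- kmeans_signal(M, k = 2, seed = 11, first_track_cols = 1:5)
  expect_equal(sort(km$sizes), c(5L, 5L))
  # label 1 = highest first-track mean
  expect_true(all(km$labels[1:5] == 1))
  km2 <- kmeans_signal(M, k = 2, seed = 11, first_track_cols = 1:5)
  expect_identical(km$labels, km2$labels)

  expect_equal(unique(kmeans_signal(M, k = 1, seed = 3)$labels), 1)
  same <- matrix(1, 4, 6)
  km3 <- kmeans_signal(same, k = 2, seed = 5)
  expect_equal(length(km3$labels), 4)
  expect_error(kmeans_signal(M, k = 20, seed = 2), "exceeds")
})
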