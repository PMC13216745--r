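test_that("high-confidence filtering applies strict thresholds", {
  pk <- data.frame(chrom = "chrA", start = 1:5 * 1000, end = 1:5 * 1000 + 100,
                   score = c(100, 150, 101, 99, 200),
                   fold_change = c(3, 2.5, 2, 5, 1.9))
  out <- filter_high_confidence(pk)
  # brute force: score > 100 AND fc > 2, both strict
  expect_equal(out, pk[pk$score > 100 & pk$fold_change > 2, ])
  expect_equal(out$score, c(150))
  expect_error(filter_high_confidence(pk[, 1:3]), "fold_change")
})

test_that("quartile assignment splits by descending score with stable ties", {
  pk <- data.frame(chrom = "chrA", start = 1:8 * 1000, end = 1:8 * 1000 + 10,
                   score = c(10, 80, 30, 70, 20, 60, 40, 50))
  q <- assign_quartiles(pk)
  expect_equal(as.vector(table(q$quartile)), rep(2L, 4))
  expect_equal(sort(q$score[q$quartile == "Q4"]), c(70, 80))
  expect_equal(sort(q$score[q$quartile == "Q1"]), c(10, 20))

  pk9 <- rbind(pk, data.frame(chrom = "chrA", start = 9000, end = 9010, score = 90))
  q9 <- assign_quartiles(pk9)
  expect_equal(as.vector(table(q9$quartile)), c(2L, 2L, 2L, 3L))  # extra in Q4

  ties <- pk; ties$score <- 5
  t1 <- assign_quartiles(ties)
  t2 <- assign_quartiles(ties)
  expect_identical(t1$quartile, t2$quartile)  # positional tie-break
  expect_equal(as.vector(t1$quartile[1:2]), c("Q4", "Q4"))
  expect_error(assign_quartiles(pk[1:3, ]), "4 peaks")
})

test_that("feature pairing respects inclusive separation bounds", {
  f <- data.frame(chrom = "chrA",
                  summit = c(0, 5000, 10000, 200000, 600000, 520000) + 1e6)
  f$start <- f$summit - 100; f$end <- f$summit + 100
  pr <- pair_features(f)
  sep <- pr$center2 - pr$center1
  expect_true(all(sep >= 1e4 & sep <= 5e5))
  # exactly 10 kb included, 5 kb excluded
  expect_true(any(sep == 1e4))
  expect_false(any(sep == 5000))
  # brute-force enumeration
  ctr <- f$summit
  brute <- 0L
  for (a in 1:5) for (b in (a + 1):6) {
    s <- abs(ctr[b] - ctr[a])
    if (s >= 1e4 && s <= 5e5) brute <- brute + 1L
  }
  expect_equal(nrow(pr), brute)
  # 600 kb apart alone -> excluded
  f2 <- data.frame(chrom = "chrA", summit = c(1e6, 1.6e6))
  f2$start <- f2$summit - 10; f2$end <- f2$summit + 10
  expect_equal(nrow(pair_features(f2)), 0)
})

test_that("aggregate grids have the stated geometry and arithmetic", {
  # w = 20 kb at 250 bp -> 80 x 80
  sim <- simulate_contacts(plain_scenario(301, n = 2e4))
  obs <- sim$contacts
  exp0 <- build_expected(obs, shuffle_params(seed = 302, sweeps = 0))
  pk <- data.frame(chrom = "chrA", summit = c(1e6, 1.1e6, 2e6, 2.2e6))
  pk$start <- pk$summit - 100; pk$end <- pk$summit + 100
  pr <- pair_features(pk)
  g <- aggregate_grid(obs, exp0, pr, w = 2e4)
  expect_equal(dim(g$enrichment), c(80, 80))
  # unshuffled duplicate expected, depth-corrected: enrichment exactly 0
  expect_true(all(g$enrichment == 0))

  # hand-built single pair: center bin O = 2, E' = 1, psi = 1 -> log2(3/2)
  obs1 <- tiny_contacts(c(100000, 100100), c(160000, 160100))
  exp1 <- tiny_contacts(c(100050, 150000), c(160050, 200000))
  pr1 <- data.frame(chrom = "chrA", center1 = 100125, center2 = 160125,
                    i = 1, j = 2)
  g1 <- aggregate_grid(obs1, exp1, pr1, w = 2000, resolution = 250,
                       depth_factor = 1)
  ctr <- central_square_stat(g1, n_c = 2)
  expect_equal(sum(g1$observed), 2)
  expect_equal(max(g1$enrichment), log2(3 / 2), tolerance = 1e-12)

  # off-end windows are skipped with a warning
  pr_edge <- data.frame(chrom = "chrA", center1 = 5000, center2 = 60000,
                        i = 1, j = 2)
  expect_warning(expect_error(aggregate_grid(obs1, exp1, pr_edge, w = 2e4),
                              "usable"), "skipped")
})

test_that("the central square indexes the documented bins", {
  g <- list(enrichment = matrix(0, 80, 80))
  class(g) <- "AggregateGrid"
  cs <- central_square_stat(g, 8)
  expect_equal(cs$rows, 37:44)  # 0-based 36..43
  expect_true(all(cs$values == 0))
  inj <- matrix(0, 80, 80)
  inj[37:44, 37:44] <- 5
  g$enrichment <- inj
  expect_equal(central_square_stat(g, 8)$mean, 5)
  expect_error(central_square_stat(g, 100), "larger")
})

test_that("count conservation holds for pooled grids", {
  sim <- simulate_contacts(plain_scenario(311, n = 5e4))
  obs <- sim$contacts
  exp0 <- build_expected(obs, shuffle_params(seed = 312, sweeps = 0))
  pk <- data.frame(chrom = "chrA", summit = seq(1e6, 2e6, by = 1e5))
  pk$start <- pk$summit - 50; pk$end <- pk$summit + 50
  g <- aggregate_grid(obs, exp0, pair_features(pk), w = 2e4)
  expect_lte(sum(g$observed), nrow(obs$cis) * g$n_pairs)
  expect_gt(sum(g$observed), 0)
})

test_that("quartile report recovers coupling and stays quiet under the null", {
  # coupled case is exercised at scale in the acceptance suite; here the
  # degenerate single-quartile path and the uncorrelated null
  sim <- simulate_contacts(plain_scenario(321, n = 1e5,
                                          chroms = c(chrA = 5e6, chrB = 5e6)))
  obs <- sim$contacts
  exp <- build_expected(obs, shuffle_params(seed = 322))
  set.seed(323)
  # peaks on a fixed grid (every quartile keeps pairable members); scores
  # uncorrelated with anything
  pk <- data.frame(chrom = rep(c("chrA", "chrB"), each = 20),
                   summit = rep(seq(5e5, 4.3e6, by = 2e5), 2))
  pk$start <- pk$summit - 200; pk$end <- pk$summit + 200
  pk$score <- runif(40, 100, 200)
  pk$fold_change <- 3
  rep <- quartile_aggregate_report(assign_quartiles(pk), obs, exp)
  expect_true(all(rep$dunn$p_adj >= rep$dunn$p - 1e-12))
  expect_true(nrow(rep$dunn) >= 1)
  expect_gt(min(rep$dunn$p_adj), 0.05)

  one_q <- assign_quartiles(pk)
  one_q <- one_q[one_q$quartile == "Q2", ]
  rep1 <- quartile_aggregate_report(one_q, obs, exp)
  expect_null(rep1$kruskal)
  expect_null(rep1$dunn)
})
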