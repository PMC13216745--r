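cs2 <- chrom_sizes(c(chrA = 5e6, chrB = 5e6))

test_that("pairs files parse with cis/trans split and canonicalization", {
  f <- withr::local_tempfile(fileext = ".pairs")
  writeLines(c("## pairs format v1.0",
               "#columns: readID chr1 pos1 chr2 pos2",
               "r1\tchrA\t100350\tchrA\t100",
               "r2\tchrA\t5000\tchrB\t6000",
               "r3\tchrB\t900\tchrB\t2000"), f)
  cs <- read_pairs(f, cs2)
  expect_equal(nrow(cs$cis), 2)
  expect_equal(nrow(cs$trans), 1)
  # pos2 < pos1 stored swapped
  expect_equal(cs$cis$pos1[1], 100)
  expect_equal(cs$cis$pos2[1], 100350)
  # round-trip through write_pairs
  g <- withr::local_tempfile(fileext = ".pairs")
  write_pairs(cs, g)
  again <- read_pairs(g, cs2)
  expect_equal(again$cis, cs$cis)

  writeLines(c("#columns: readID chr1 pos1 chr2 pos2",
               "r1\tchrA\t100\tchrA\t6000001"), f)
  expect_error(read_pairs(f, cs2), "bounds")
  writeLines(c("#columns: readID chr1 pos1 chr2 pos2",
               "r1\tchrZ\t100\tchrZ\t500"), f)
  expect_error(read_pairs(f, cs2), "chrZ")
})

test_that("minimum-distance filter is strict below the threshold", {
  cs <- tiny_contacts(pos1 = c(1000, 1000, 1000, 5000),
                      pos2 = c(1199, 1200, 1500, 5100))
  out <- filter_min_distance(cs, 200)
  expect_equal(out$cis$pos2, c(1200, 1500))  # 199 removed, 200 retained
  expect_equal(attr(out, "n_removed"), 2L)
  # brute-force equality on a random mixed fixture
  set.seed(5)
  p1 <- sort(round(runif(10, 1, 1e5)))
  p2 <- p1 + round(runif(10, 0, 600))
  cs <- tiny_contacts(p1, p2)
  out <- filter_min_distance(cs, 200)
  expect_equal(out$cis, cs$cis[(cs$cis$pos2 - cs$cis$pos1) >= 200, ],
               ignore_attr = TRUE)
  # trans untouched
  cstr <- contact_set(data.frame(chrom = character(0), pos1 = numeric(0),
                                 pos2 = numeric(0)), cs2,
                      trans = data.frame(chrom1 = "chrA", pos1 = 10,
                                         chrom2 = "chrB", pos2 = 20))
  expect_equal(nrow(filter_min_distance(cstr)$trans), 1)
})

test_that("binning uses floor((pos-1)/resolution) and conserves counts", {
  cs <- tiny_contacts(100, 100350)
  m <- bin_contacts(cs, 400)
  tri <- Matrix::summary(m$matrices$chrA)
  # positions 100 -> bin 0, 100350 -> bin 250 (0-based)
  expect_equal(tri$i - 1L, 0)
  expect_equal(tri$j - 1L, 250)
  expect_equal(tri$x, 1)

  empty <- contact_set(data.frame(chrom = character(0), pos1 = numeric(0),
                                  pos2 = numeric(0)), cs2)
  expect_equal(sum(bin_contacts(empty, 1000)$matrices$chrA), 0)

  sim <- simulate_contacts(plain_scenario(3, n = 1e4))
  mb <- bin_contacts(sim$contacts, 5000)
  expect_equal(sum(vapply(mb$matrices, sum, 0)), 1e4)
})

test_that("filtering commutes with binning when min_sep is a bin multiple", {
  sim <- simulate_contacts(plain_scenario(9, n = 5000,
                                          chroms = c(chrA = 1e6)))
  cs <- sim$contacts
  res <- 100  # min_sep 200 = 2 bins
  a <- bin_contacts(filter_min_distance(cs, 200), res)$matrices$chrA
  b <- bin_contacts(cs, res)$matrices$chrA
  tri <- Matrix::summary(b)
  keepable <- tri[tri$j - tri$i >= 2, ]
  # every bin pair at >= 2 bins separation is identical in both routes
  expect_equal(Matrix::summary(a)[Matrix::summary(a)$j - Matrix::summary(a)$i >= 2, ],
               keepable, ignore_attr = TRUE)
})

test_that("iterative correction equalizes marginals and matches an IPF oracle", {
  # constant positive matrix: uniform weights already balanced
  M <- Matrix::sparseMatrix(i = rep(1:4, times = 4:1),
                            j = unlist(lapply(1:4, function(i) i:4)),
                            x = 1, dims = c(4, 4))
  bm <- structure(list(resolution = 1000, matrices = list(chrA = M),
                       chromsizes = chrom_sizes(c(chrA = 4000)),
                       weights = NULL, masked = NULL),
                  class = "BinnedMatrix")
  bal <- ice_balance(bm)
  w <- bal$weights$chrA
  S <- M + Matrix::t(M) - Matrix::Diagonal(x = Matrix::diag(M))
  s <- Matrix::rowSums(Matrix::Diagonal(x = 1 / w) %*% S %*% Matrix::Diagonal(x = 1 / w))
  expect_lt(max(abs(s / mean(s) - 1)), 1e-5)

  # heavy-row toy vs an independent dense Sinkhorn oracle
  A <- matrix(c(10, 4, 2, 1,
                 4, 3, 1, 1,
                 2, 1, 2, 1,
                 1, 1, 1, 1), 4, 4, byrow = TRUE)
  A[lower.tri(A)] <- 0
  M2 <- Matrix::Matrix(A, sparse = TRUE)
  bm$matrices$chrA <- methods::as(M2, "generalMatrix")
  bal2 <- ice_balance(bm, tol = 1e-9, max_iter = 2000)
  w2 <- bal2$weights$chrA
  # oracle: dense symmetric iterative proportional scaling
  S2 <- A + t(A) - diag(diag(A))
  b <- rep(1, 4)
  for (it in 1:5000) {
    s <- rowSums(S2 / outer(b, b))
    b <- b * s / mean(s)
  }
  b <- b / mean(b)
  expect_equal(w2 / mean(w2), b, tolerance = 1e-6)

  # all-zero row is masked and excluded
  A3 <- A; A3[3, ] <- 0; A3[, 3] <- 0
  bm$matrices$chrA <- methods::as(Matrix::Matrix(A3, sparse = TRUE), "generalMatrix")
  bal3 <- ice_balance(bm)
  expect_true(bal3$masked$chrA[3])
  expect_false(any(bal3$masked$chrA[-3]))
})

test_that("decay curves normalize and match the analytic field", {
  cs <- tiny_contacts(rep(1000, 5), rep(1500, 5))
  d <- estimate_decay(cs)
  expect_equal(sum(d$mass), 1)
  expect_equal(max(d$mass), 1)  # all separations in one bin

  # alpha = 1 simulation: bin masses match analytic integrals within 3 SE.
  # Sub-2 kb bins are excluded: the 150 bp fragment lattice redistributes
  # distances within them, which the continuous integral cannot capture.
  sim <- simulate_contacts(plain_scenario(21, n = 1e5))
  dec <- estimate_decay(sim$contacts)
  L <- 5e6
  edges <- dec$edges
  analytic <- vapply(seq_len(length(edges) - 1), function(b) {
    lo <- min(edges[b], L); hi <- min(edges[b + 1], L)
    if (hi <= lo) return(0)
    s <- seq(lo, hi, length.out = 2001)
    f <- (L - s) / s
    sum(diff(s) * (f[-1] + f[-length(f)]) / 2)
  }, 0)
  analytic <- analytic / sum(analytic)
  se <- sqrt(analytic * (1 - analytic) / dec$n_cis)
  coarse <- edges[-length(edges)] >= 2000
  expect_true(all(abs(dec$mass - analytic)[coarse] <= (3 * se + 1e-4)[coarse]))

  expect_error(estimate_decay(
    contact_set(data.frame(chrom = character(0), pos1 = numeric(0),
                           pos2 = numeric(0)), cs2)), "cis")
})

test_that("observed/expected flattens the decay and preserves planted boxes", {
  sim <- simulate_contacts(plain_scenario(31, n = 1e5))
  mb <- bin_contacts(sim$contacts, 50000)
  oe <- observed_over_expected(mb)
  tri <- Matrix::summary(oe$chrA$oe)
  per_diag <- tapply(tri$x, tri$j - tri$i, mean)
  # off-diagonal O/E means stay near 1 (entries exist at most separations)
  dense_diags <- names(per_diag)[as.integer(names(per_diag)) < 50]
  expect_true(all(abs(unlist(per_diag[dense_diags]) - 1) < 0.25))
  expect_lt(abs(mean(unlist(per_diag[dense_diags])) - 1), 0.05)

  # planted loop box carries approximately its strength multiplier
  sc <- one_loop_scenario(41, strength = 8, n = 1e6, width = 6000)
  sim2 <- simulate_contacts(sc)
  mb2 <- bin_contacts(sim2$contacts, 2000)
  oe2 <- observed_over_expected(mb2)
  b1 <- floor((2501000 - 1) / 2000); b2 <- floor((2561000 - 1) / 2000)
  box <- as.matrix(oe2$chrA$oe[(b1 - 1):(b1 + 1) + 1, (b2 - 1):(b2 + 1) + 1])
  expect_gt(max(box), 4)

  # zero matrix -> fully masked
  empty <- contact_set(data.frame(chrom = character(0), pos1 = numeric(0),
                                  pos2 = numeric(0)), cs2)
  oe0 <- observed_over_expected(bin_contacts(empty, 1e5))
  expect_true(all(oe0$chrA$masked))
})
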