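# small helper: BinnedMatrix straight from a dense upper-triangular matrix
dense_bm <- function(A, resolution = 1000) {
  A[lower.tri(A)] <- 0
  structure(list(resolution = resolution,
                 matrices = list(chrA = methods::as(Matrix::Matrix(A, sparse = TRUE),
                                                   "generalMatrix")),
                 chromsizes = chrom_sizes(c(chrA = nrow(A) * resolution)),
                 weights = NULL, masked = NULL),
            class = "BinnedMatrix")
}

test_that("a flat matrix yields no confident candidates", {
  set.seed(42)
  n <- 120
  A <- matrix(0, n, n)
  for (d in 3:60) {
    idx <- seq_len(n - d)
    A[cbind(idx, idx + d)] <- rpois(length(idx), 20)
  }
  bm <- ice_balance(dense_bm(A))
  cand <- detect_candidates(bm, d_min = 3000, d_max = 60000,
                            params = loop_call_params())
  expect_true(nrow(cand) == 0 || min(cand$fdr) > 0.1)
})

test_that("a single planted peak is found at its exact bin pair", {
  n <- 120
  A <- matrix(0, n, n)
  for (d in 3:60) {
    idx <- seq_len(n - d)
    A[cbind(idx, idx + d)] <- 20
  }
  A[50, 50 + 20] <- 150  # deterministic construction, no noise
  bm <- ice_balance(dense_bm(A))
  cand <- detect_candidates(bm, d_min = 3000, d_max = 60000,
                            params = loop_call_params())
  top <- cand[cand$fdr <= 0.1, ]
  expect_equal(nrow(top), 1)
  expect_equal(top$bin1, 49)  # 0-based
  expect_equal(top$bin2, 69)
})

test_that("the FDR scan matches brute force and includes grid endpoints", {
  grid <- seq(1e-4, 0.1, by = 1e-4)
  expect_equal(grid[1], 1e-4)
  expect_equal(grid[length(grid)], 0.1)
  cand <- data.frame(chrom = "chrA", bin1 = c(10, 20, 30, 40, 50, 60),
                     bin2 = c(30, 45, 60, 75, 90, 105),
                     resolution = 1000, count = 9,
                     fdr = c(.001, .002, .01, .02, .05, .09))
  gold <- data.frame(chrom1 = "chrA",
                     start1 = c(10, 20) * 1000 + 1, end1 = c(11, 21) * 1000,
                     chrom2 = "chrA",
                     start2 = c(30, 45) * 1000 + 1, end2 = c(31, 46) * 1000)
  scan <- fdr_scan(cand, gold, resolution = 1000, fdr_grid = grid)
  # independent brute force over the grid
  brute <- sapply(grid, function(t) {
    det <- cand[cand$fdr <= t, ]
    if (nrow(det) == 0) return(c(0, 0, 0))
    gd <- sum(sapply(seq_len(nrow(gold)), function(g) {
      gb1 <- floor((floor((gold$start1[g] + gold$end1[g]) / 2) - 1) / 1000)
      gb2 <- floor((floor((gold$start2[g] + gold$end2[g]) / 2) - 1) / 1000)
      any(abs(det$bin1 - gb1) <= 1 & abs(det$bin2 - gb2) <= 1)
    }))
    c(nrow(det), gd, gd / nrow(det))
  })
  expect_equal(scan$table$n_detected, brute[1, ])
  expect_equal(scan$table$n_gold_detected, brute[2, ])
  expect_equal(scan$table$r_gs, brute[3, ])
  # selection: max r_GS, ties -> most detections, then smallest threshold
  expect_equal(scan$selected, grid[order(-brute[3, ], -brute[1, ], grid)[1]])
  expect_equal(scan$selected, 0.002)
  expect_equal(scan$r_gs_max, 1.0)

  # gold matching nothing: all r_GS zero, smallest threshold, warning
  far_gold <- data.frame(chrom1 = "chrA", start1 = 900001, end1 = 901000,
                         chrom2 = "chrA", start2 = 950001, end2 = 951000)
  expect_warning(s2 <- fdr_scan(cand, far_gold, 1000, grid), "matches no")
  expect_true(all(s2$table$r_gs == 0))
  # all-zero r_GS: the tie rule keeps the most inclusive threshold (the
  # smallest t detecting every candidate)
  expect_equal(s2$selected, 0.09)
  expect_error(fdr_scan(cand, gold[0, ], 1000, grid), "nonempty")
})

test_that("merging joins loops closer than one bin, transitively", {
  cand <- data.frame(chrom = "chrA",
                     bin1 = c(10, 10, 11, 30), bin2 = c(40, 40, 41, 80),
                     resolution = 2000, count = c(5, 9, 7, 4),
                     fdr = c(.01, .001, .005, .02))
  # candidates 1-2 identical bins, 3 adjacent (half-bin midpoint offset is
  # impossible on a lattice; adjacent bins are < 1 bin apart only via
  # midpoints 1 bin apart -> test the strict rule explicitly)
  m <- merge_within_bin(cand, 2000)
  # candidates 1 and 2 share the exact bin pair -> merged to the lowest FDR
  expect_true(all(c(.001, .005, .02) %in% m$fdr))
  expect_equal(nrow(m), 3)

  # fractional midpoints via different resolutions are exercised in the
  # cross-resolution merge; here the chain rule A~B~C
  chain <- data.frame(chrom = "chrA",
                      bin1 = c(10, 10, 10), bin2 = c(40, 40, 40),
                      resolution = 2000, count = c(1, 2, 3),
                      fdr = c(.03, .02, .01))
  expect_equal(nrow(merge_within_bin(chain, 2000)), 1)
  two_apart <- data.frame(chrom = "chrA", bin1 = c(10, 12), bin2 = c(40, 42),
                          resolution = 2000, count = 1, fdr = .01)
  expect_equal(nrow(merge_within_bin(two_apart, 2000)), 2)
})

test_that("recentering moves anchors to the score maximum with +-2 kb halo", {
  loops <- data.frame(chrom1 = "chrA", start1 = 100001, end1 = 110000,
                      chrom2 = "chrA", start2 = 200001, end2 = 210000,
                      trans = FALSE)
  # score map at 1 kb: maximum 1.5 kb off the area centre
  mp <- expand.grid(bin1 = 100:109, bin2 = 200:209)
  mp$score <- 1
  mp$score[mp$bin1 == 106 & mp$bin2 == 206] <- 50
  mp$n <- 1L
  smap <- structure(list(resolution = 1000, maps = list(chrA = mp)),
                    class = "ScoreMap")
  rc <- recenter_on_max(loops, smap, halo = 2000)
  expect_true(rc$recentered)
  expect_equal(rc$summit1, 106500)
  expect_equal(rc$end1 - rc$start1, 4000)  # +-2 kb
  expect_equal(rc$start2, 206500 - 2000)
  # brute-force argmax agreement on the 10x10 area
  best <- mp[which.max(mp$score), ]
  expect_equal(rc$summit1, (best$bin1 + 0.5) * 1000)

  # flat scores: unchanged centre via the tie rule
  mp$score <- 1
  smap$maps$chrA <- mp
  rc2 <- recenter_on_max(loops, smap, halo = 2000)
  # closest bin pair to the original centre (105000.5, 205000.5)
  expect_true(rc2$summit1 %in% c(104500, 105500))
  # no scored bins in the area: flagged, kept
  smap$maps$chrA <- mp[mp$bin1 > 500, ]
  rc3 <- recenter_on_max(loops, smap, halo = 2000)
  expect_false(rc3$recentered)
  expect_equal(rc3$start1, loops$start1)
})

test_that("call_loops runs end to end, masks and calibrates", {
  # pericentromeric planting: name the chromosome chr2R so the default
  # mask applies to its first 5.756 Mb
  sc <- synthetic_scenario(
    seed = 401, chrom_sizes = c(chr2R = 8e6), n_contacts = 2.5e6,
    tads = data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), multiplier = numeric(0)),
    loops = data.frame(chrom = "chr2R",
                       center1 = c(1001000, 6501000),
                       center2 = c(1061000, 6561000),
                       width = 2000, strength = 12))
  sim <- simulate_contacts(sc)
  obs <- filter_min_distance(sim$contacts)
  gold <- gold_standard_from_truth(sc)
  params <- loop_call_params(schedule = data.frame(resolution = 2000,
                                                   d_min = 1e4, d_max = 4e5))
  loops <- call_loops(obs, NULL, gold, params)
  # the pericentromeric loop is masked out but logged; the other is called
  expect_gte(nrow(loops), 1)
  expect_true(all(loops$start1 > 5756000))
  expect_true(any(abs(attr(loops, "masked")$start1 - 1001000) < 5000))
  expect_true(any(abs(loops$start1 - 6501000) < 5000))
  expect_s3_class(attr(loops, "calibration")[[1]], "FDRScanResult")
  expect_true(all(attr(loops, "review")$review))

  # empty gold falls back to a fixed threshold with a prominent warning
  expect_warning(call_loops(obs, NULL, gold[0, ], params), "GOLD")
})
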