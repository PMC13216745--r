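# Pooled log2(Observed/Expected) enrichment grids around feature pairs and
# the quartile analysis built on them: peak filtering, score quartiles,
# feature pairing at 10-500 kb separation, w x w aggregate windows at 250 bp
# resolution, and the central-square statistic.

#' High-confidence peak filter
#'
#' Retains peaks with score strictly above \code{min_score} and fold change
#' strictly above \code{min_fold_change} (defaults 100 and 2).
#'
#' @param peaks Peak data.frame with \code{score} and \code{fold_change}.
#' @param min_score,min_fold_change Strict lower thresholds.
#' @return Filtered peak data.frame.
#' @export
filter_high_confidence <- function(peaks, min_score = 100, min_fold_change = 2) {
  if (!all(c("score", "fold_change") %in% names(peaks)))
    stop("peaks need score and fold_change columns")
  peaks[peaks$score > min_score & peaks$fold_change > min_fold_change, ,
        drop = FALSE]
}

#' Assign peaks to score quartiles
#'
#' Peaks are stably sorted by descending score (ties broken by chromosome
#' then start) and split into four near-equal groups; Q4 holds the highest
#' scores and receives extra members first when n is not divisible by 4.
#'
#' @param peaks Peak data.frame (>= 4 rows).
#' @return \code{peaks} with an ordered factor column \code{quartile}
#'   (levels Q1 < Q2 < Q3 < Q4).
#' @export
assign_quartiles <- function(peaks) {
  n <- nrow(peaks)
  if (n < 4) stop("need at least 4 peaks to form quartiles")
  o <- order(-peaks$score, peaks$chrom, peaks$start)
  sizes <- rep(n %/% 4, 4)
  extra <- n %% 4
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1  # Q4 first
  lab <- rep(c("Q4", "Q3", "Q2", "Q1"), times = sizes)
  peaks$quartile <- factor(NA, levels = c("Q1", "Q2", "Q3", "Q4"), ordered = TRUE)
  peaks$quartile[o] <- factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"), ordered = TRUE)
  peaks
}

.feature_centers <- function(features) {
  if ("summit" %in% names(features)) features$summit
  else floor((features$start + features$end) / 2)
}

#' Pair features by center separation
#'
#' All unordered same-chromosome pairs whose centers are separated by at
#' least \code{min_sep} and not more than \code{max_sep} bp (both bounds
#' inclusive).
#'
#' @param features Interval/peak data.frame (centers from \code{summit}
#'   when present, else interval midpoint).
#' @param min_sep,max_sep Separation bounds in bp (defaults 10 kb, 500 kb).
#' @return data.frame(chrom, center1, center2, i, j) with
#'   \code{center1 < center2}.
#' @export
pair_features <- function(features, min_sep = 1e4, max_sep = 5e5) {
  ctr <- .feature_centers(features)
  out <- list()
  for (ch in unique(features$chrom)) {
    idx <- which(features$chrom == ch)
    if (length(idx) < 2) next
    o <- idx[order(ctr[idx])]
    cc <- ctr[o]
    for (a in seq_len(length(o) - 1)) {
      sep <- cc[(a + 1):length(o)] - cc[a]
      sel <- which(sep >= min_sep & sep <= max_sep)
      if (length(sel))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, center1 = cc[a], center2 = cc[a + sel],
          i = o[a], j = o[a + sel])
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), center1 = numeric(0),
                      center2 = numeric(0), i = integer(0), j = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# contacts split by chromosome and sorted by pos1, computed once and
# reused across many aggregate windows
.sort_cis <- function(cis) {
  lapply(split(cis[, c("pos1", "pos2")], cis$chrom), function(df) {
    o <- order(df$pos1)
    list(p1 = df$pos1[o], p2 = df$pos2[o])
  })
}

# counts of one (pre-sorted) contact set accumulated into the pooled
# w x w grid
.accumulate_grid <- function(sorted, pairs, w, resolution) {
  side <- as.integer(w / resolution)
  G <- matrix(0, side, side)
  per_pair <- numeric(nrow(pairs))
  sp <- split(seq_len(nrow(pairs)), pairs$chrom)
  for (ch in names(sp)) {
    if (is.null(sorted[[ch]])) next
    p1 <- sorted[[ch]]$p1; p2 <- sorted[[ch]]$p2
    for (r in sp[[ch]]) {
      lo1 <- pairs$center1[r] - w / 2
      lo2 <- pairs$center2[r] - w / 2
      k <- findInterval(c(lo1 - 0.5, lo1 + w - 0.5), p1)
      if (k[2] <= k[1]) next
      rng <- (k[1] + 1):k[2]
      y <- p2[rng]
      keep <- y >= lo2 & y < lo2 + w
      if (!any(keep)) next
      u <- floor((p1[rng][keep] - lo1) / resolution) + 1
      v <- floor((y[keep] - lo2) / resolution) + 1
      tab <- table(factor(u, levels = 1:side), factor(v, levels = 1:side))
      G <- G + as.matrix(tab)
      per_pair[r] <- sum(keep)
    }
  }
  list(grid = G, per_pair = per_pair)
}

#' Pooled aggregate enrichment grid around feature pairs
#'
#' Observed and expected contacts are accumulated into w x w windows
#' centred on each pair's (center1, center2) at the given resolution;
#' expected counts are divided by the expected model's depth factor so both
#' grids are on the same scale, and enrichment is
#' \code{log2((O + psi)/(E' + psi))}.
#'
#' @param obs Observed \code{ContactSet}.
#' @param exp Expected \code{ContactSet}/\code{ExpectedContacts}.
#' @param pairs \code{\link{pair_features}} output.
#' @param w Window size in bp (must be divisible by \code{resolution});
#'   20 kb for peak pairs, 8 kb for loops.
#' @param resolution Grid resolution in bp (default 250).
#' @param pseudocount psi added to both counts (default 1).
#' @param depth_factor Expected depth correction; defaults to the expected
#'   set's provenance, falling back to the cis-count ratio.
#' @param obs_sorted,exp_sorted Optional pre-sorted contact indices (from
#'   the internal sorter) to avoid re-sorting across repeated calls.
#' @return Object of class \code{"AggregateGrid"} with the pooled
#'   \code{observed}, depth-corrected \code{expected} and
#'   \code{enrichment} grids, \code{n_pairs} used and per-pair central
#'   counts.
#' @export
aggregate_grid <- function(obs, exp, pairs, w, resolution = 250,
                           pseudocount = 1, depth_factor = NULL,
                           obs_sorted = NULL, exp_sorted = NULL) {
  if (w %% resolution != 0) stop("w must be divisible by resolution")
  if (nrow(pairs) == 0) stop("no feature pairs")
  if (is.null(depth_factor)) {
    depth_factor <- if (!is.null(exp$provenance))
      exp$provenance$params$depth_factor
    else nrow(exp$cis) / nrow(obs$cis)
  }
  L <- obs$chromsizes[pairs$chrom]
  ok <- pairs$center1 - w / 2 >= 0 & pairs$center2 + w / 2 <= L
  if (any(!ok)) warning(sum(!ok), " pair(s) skipped: window off chromosome end")
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no usable feature pairs")
  if (is.null(obs_sorted)) obs_sorted <- .sort_cis(obs$cis)
  if (is.null(exp_sorted)) exp_sorted <- .sort_cis(exp$cis)
  O <- .accumulate_grid(obs_sorted, pairs, w, resolution)
  E <- .accumulate_grid(exp_sorted, pairs, w, resolution)
  Ecorr <- E$grid / depth_factor
  enr <- log2((O$grid + pseudocount) / (Ecorr + pseudocount))
  structure(list(w = w, resolution = resolution, n_pairs = nrow(pairs),
                 observed = O$grid, expected = Ecorr, enrichment = enr,
                 pseudocount = pseudocount, depth_factor = depth_factor,
                 pairs = pairs,
                 per_pair_obs = O$per_pair, per_pair_exp = E$per_pair / depth_factor),
            class = "AggregateGrid")
}

#' @export
print.AggregateGrid <- function(x, ...) {
  cat("AggregateGrid: ", x$w, " bp window at ", x$resolution, " bp (",
      nrow(x$enrichment), "x", ncol(x$enrichment), "), ", x$n_pairs,
      " pairs, central mean ",
      signif(central_square_stat(x)$mean, 3), "\n", sep = "")
  invisible(x)
}

#' Central-square statistic of an aggregate grid
#'
#' Extracts the n_c x n_c central bins of the enrichment grid (for an
#' even-sided grid the square is centred on side/2 with lower-left bias:
#' 0-based rows/cols side/2 - n_c/2 ... side/2 + n_c/2 - 1).
#'
#' @param g \code{AggregateGrid}.
#' @param n_c Side of the central square (default 8).
#' @return List with the central \code{values} matrix and their
#'   \code{mean}.
#' @export
central_square_stat <- function(g, n_c = 8) {
  side <- nrow(g$enrichment)
  if (n_c > side) stop("central square larger than grid")
  lo <- side %/% 2 - n_c %/% 2 + 1
  idx <- lo:(lo + n_c - 1)
  vals <- g$enrichment[idx, idx]
  list(values = vals, mean = mean(vals), rows = idx)
}

#' Per-quartile aggregate enrichment report
#'
#' Runs the quartile version of the aggregate analysis: peaks are paired
#' within their score quartile, a pooled enrichment grid is computed per
#' quartile, and the central-square values are compared across quartiles
#' with Kruskal-Wallis followed by Dunn's post hoc test with
#' Benjamini-Hochberg correction.
#'
#' @param peaks Peak data.frame; quartiles are assigned if absent.
#' @param obs,exp Observed and expected \code{ContactSet}s.
#' @param w,resolution,n_c Grid geometry (defaults 20 kb, 250 bp, 8).
#' @param min_sep,max_sep Pairing bounds (defaults 10 kb, 500 kb).
#' @param cross_quartile Also pair peaks across quartiles (default FALSE:
#'   pairs are formed within each quartile).
#' @return List with per-quartile central means, the central-value groups,
#'   the Kruskal-Wallis result and the Dunn/BH pairwise table. Quartiles
#'   without usable pairs are reported as empty and excluded from the
#'   comparisons.
#' @export
quartile_aggregate_report <- function(peaks, obs, exp, w = 2e4,
                                      resolution = 250, n_c = 8,
                                      min_sep = 1e4, max_sep = 5e5,
                                      cross_quartile = FALSE) {
  if (!"quartile" %in% names(peaks)) peaks <- assign_quartiles(peaks)
  qs <- levels(peaks$quartile)
  obs_sorted <- .sort_cis(obs$cis)
  exp_sorted <- .sort_cis(exp$cis)
  groups <- list()
  central_mean <- setNames(rep(NA_real_, length(qs)), qs)
  grids <- list()
  for (q in qs) {
    sub <- if (cross_quartile) peaks else peaks[peaks$quartile == q, , drop = FALSE]
    if (nrow(sub) < 2) next
    pr <- pair_features(sub, min_sep, max_sep)
    if (!cross_quartile && nrow(pr) == 0) next
    g <- tryCatch(aggregate_grid(obs, exp, pr, w, resolution,
                                 obs_sorted = obs_sorted,
                                 exp_sorted = exp_sorted),
                  error = function(e) NULL)
    if (is.null(g)) next
    cs <- central_square_stat(g, n_c)
    groups[[q]] <- as.vector(cs$values)
    central_mean[q] <- cs$mean
    grids[[q]] <- g
  }
  kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
  dunn <- if (length(groups) >= 2) dunn_bh(groups) else NULL
  list(central_mean = central_mean, groups = groups, kruskal = kw,
       dunn = dunn, grids = grids,
       empty_quartiles = qs[!qs %in% names(groups)])
}
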