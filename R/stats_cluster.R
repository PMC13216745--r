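# Nonparametric group comparisons (Kruskal-Wallis, Dunn's post hoc test
# with Benjamini-Hochberg correction), loop sharing across conditions, and
# k-means clustering of signal matrices around features.

#' Kruskal-Wallis test on a list of groups
#'
#' Rank-based H with tie correction (delegates to
#' \code{stats::kruskal.test}).
#'
#' @param groups Named list of numeric vectors (>= 2 nonempty groups).
#' @return List with \code{H}, \code{p} and \code{df}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise test with BH correction
#'
#' Pairwise z statistics from pooled-rank mean differences with the
#' tie-corrected variance
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' two-sided p-values, Benjamini-Hochberg adjusted across all pairs.
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame(group1, group2, z, p, p_adj).
#' @export
dunn_bh <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(v0 * (1 / n[[i]] + 1 / n[[j]]))
    # v0 = 0 when every pooled value is tied: no evidence of difference
    z[k] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Classify loop sharing across conditions
#'
#' Each loop of the reference condition (the first element) is matched
#' against every other condition: two loops match when both anchor
#' midpoints are within \code{tolerance} bp on the same chromosome. The
#' classes are \code{all} (shared with every other condition),
#' \code{only_<X>} (shared exclusively with condition X, or a +-joined
#' list when shared with a strict subset) and \code{specific}.
#'
#' @param loopsets Named list of loop data.frames; the first is the
#'   reference.
#' @param tolerance Anchor matching tolerance in bp.
#' @return List with the per-loop \code{class} vector, the class
#'   \code{counts} and \code{percentages}.
#' @export
loop_sharing <- function(loopsets, tolerance) {
  if (length(loopsets) < 2) stop("need at least 2 conditions")
  ref <- loopsets[[1]]
  others <- loopsets[-1]
  mid <- function(lp) list(c1 = (lp$start1 + lp$end1) / 2,
                           c2 = (lp$start2 + lp$end2) / 2)
  rm <- mid(ref)
  match_in <- vapply(others, function(other) {
    om <- mid(other)
    vapply(seq_len(nrow(ref)), function(i) {
      any(other$chrom1 == ref$chrom1[i] & other$chrom2 == ref$chrom2[i] &
            abs(om$c1 - rm$c1[i]) <= tolerance &
            abs(om$c2 - rm$c2[i]) <= tolerance)
    }, TRUE)
  }, logical(nrow(ref)))
  match_in <- matrix(match_in, nrow = nrow(ref),
                     dimnames = list(NULL, names(others)))
  cls <- apply(match_in, 1, function(hit) {
    if (all(hit)) "all"
    else if (!any(hit)) "specific"
    else paste0("only_", paste(names(others)[hit], collapse = "+"))
  })
  counts <- table(cls)
  list(class = cls, counts = counts,
       percentages = 100 * as.numeric(counts) / nrow(ref))
}

#' Extract a signal matrix around feature centers
#'
#' Mean track value per bin across [center - flank, center + flank] for
#' every feature; bins extending past either chromosome end are masked NA.
#' bedGraph step functions are integrated exactly.
#'
#' @param track Interval data.frame with a \code{value} column (bedGraph
#'   content in internal coordinates).
#' @param features Interval/peak data.frame (centers from \code{summit} or
#'   midpoint).
#' @param flank Half-window in bp.
#' @param n_bins Number of bins across the window.
#' @param chromsizes Optional \code{ChromSizes} for right-edge clipping.
#' @return Numeric matrix (features x bins) of class \code{"SignalMatrix"}.
#' @export
extract_signal_matrix <- function(track, features, flank, n_bins,
                                  chromsizes = NULL) {
  stopifnot(flank > 0, n_bins >= 1)
  ctr <- .feature_centers(features)
  M <- matrix(NA_real_, nrow(features), n_bins)
  for (ch in unique(features$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    # cumulative integral of the step function at breakpoints
    brk <- c(tr$start, tr$end + 1)
    o <- order(brk)
    # integral from -Inf to x of value(t) dt, piecewise linear in x
    integral <- function(x) {
      x <- pmax(pmin(x, max(tr$end) + 1), min(tr$start))
      ii <- findInterval(x, tr$start)
      ii[ii == 0] <- 1
      base <- c(0, cumsum(tr$value * (tr$end - tr$start + 1)))[ii]
      inside <- pmin(pmax(x - tr$start[ii], 0), tr$end[ii] - tr$start[ii] + 1)
      base + tr$value[ii] * inside
    }
    L <- if (!is.null(chromsizes)) chromsizes[[ch]] else max(tr$end)
    rows <- which(features$chrom == ch)
    edges_rel <- seq(-flank, flank, length.out = n_bins + 1)
    for (r in rows) {
      edges <- ctr[r] + edges_rel
      lo <- pmax(edges[-length(edges)], 1)
      hi <- pmin(edges[-1], L + 1)
      len <- hi - lo
      vals <- ifelse(len > 0, (integral(hi) - integral(lo)) / len, NA_real_)
      vals[edges[-length(edges)] < 1 | edges[-1] > L + 1] <- NA_real_
      M[r, ] <- vals
    }
  }
  structure(M, class = c("SignalMatrix", "matrix", "array"))
}

#' k-means clustering of (concatenated) signal matrices
#'
#' Rows are z-score normalized across the concatenated tracks (masked NA
#' cells are imputed with the row mean before scaling), clustered with
#' \code{stats::kmeans} under a fixed seed with \code{n_init} restarts, and
#' labels are relabeled by descending cluster mean of the first track for
#' stability.
#'
#' @param mat \code{SignalMatrix} or a cbind of several (features x bins).
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param n_init Random restarts (default 10).
#' @param normalize \code{"zscore"} (default), \code{"quantile"} (rank
#'   scaling to [0,1] per row) or \code{"none"}.
#' @param first_track_cols Columns of the first track used for relabeling
#'   (default: first half when one matrix, else all columns).
#' @return List with \code{labels} (1 = highest first-track signal),
#'   \code{profiles} (cluster x column means of the input matrix) and
#'   \code{sizes}.
#' @export
kmeans_signal <- function(mat, k, seed, n_init = 10,
                          normalize = c("zscore", "quantile", "none"),
                          first_track_cols = NULL) {
  normalize <- match.arg(normalize)
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  if (is.null(first_track_cols)) first_track_cols <- seq_len(ncol(mat))
  X <- mat
  for (r in seq_len(nrow(X))) {
    na <- is.na(X[r, ])
    if (any(na)) X[r, na] <- mean(X[r, !na])
  }
  X <- switch(normalize,
    zscore = t(apply(X, 1, function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })),
    quantile = t(apply(X, 1, function(v) (rank(v) - 1) / max(1, length(v) - 1))),
    none = X)
  set.seed(seed)
  if (nrow(unique(X)) < k) {
    # fewer distinct rows than centers: everything collapses onto one
    # effective centroid
    labels <- rep(1L, nrow(mat))
    return(list(labels = labels,
                profiles = matrix(colMeans(mat, na.rm = TRUE), 1,
                                  dimnames = list(NULL, colnames(mat))),
                sizes = c(nrow(mat), rep(0L, k - 1))))
  }
  km <- kmeans(X, centers = k, nstart = n_init, iter.max = 50)
  # relabel by descending mean of the first track
  track_mean <- vapply(seq_len(k), function(cl)
    mean(mat[km$cluster == cl, first_track_cols], na.rm = TRUE), 0)
  relabel <- match(seq_len(k), order(track_mean, decreasing = TRUE))
  labels <- relabel[km$cluster]
  profiles <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(mat[labels == cl, , drop = FALSE], na.rm = TRUE)))
  list(labels = labels, profiles = profiles,
       sizes = tabulate(labels, nbins = k))
}
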