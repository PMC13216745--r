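# Per-contact signed Kolmogorov-Smirnov enrichment scores: each observed
# contact is compared, through the distance distributions of its k nearest
# observed and k_exp nearest expected neighbours in the (pos1, pos2) plane,
# against the shuffled expected model.  Scores live on a -100..+100 scale;
# positive means local contact enrichment over the null.

#' Scoring parameters
#'
#' @param k Observed neighbour count (default 250).
#' @param k_exp Expected neighbour count (default 500; the default ratio
#'   k_exp/k equals the expected model's depth factor, so that under the
#'   null both samples probe the same distance quantile).
#' @return List of class \code{"ScoringParams"}.
#' @export
scoring_params <- function(k = 250, k_exp = 500) {
  stopifnot(k >= 2, k_exp >= 2)
  structure(list(k = as.integer(k), k_exp = as.integer(k_exp)),
            class = "ScoringParams")
}

#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' \code{D} is the supremum of |F1 - F2| over the empirical CDFs (with the
#' \code{<=} convention, so exact ties are well defined); \code{signed_D}
#' is F1 - F2 at the argmax, ties broken at the smallest value. Positive
#' \code{signed_D} means sample1 is stochastically smaller (denser at short
#' distances).
#'
#' @param sample1,sample2 Nonempty numeric vectors.
#' @return List with \code{D} in [0,1] and \code{signed_D} in [-1,1].
#' @export
ks_d <- function(sample1, sample2) {
  if (length(sample1) == 0L || length(sample2) == 0L)
    stop("ks_d requires nonempty samples")
  a <- sort(sample1); b <- sort(sample2)
  n1 <- length(a); n2 <- length(b)
  v <- sort(unique(c(a, b)))
  # exact integer arithmetic so argmax ties are resolved deterministically
  # (first = smallest value), consistent with the compiled scorer
  di <- findInterval(v, a) * n2 - findInterval(v, b) * n1
  i <- which.max(abs(di))  # first maximum = smallest value
  list(D = abs(di[i]) / (n1 * n2), signed_D = di[i] / (n1 * n2))
}

#' Score observed contacts against the expected model
#'
#' For each queried cis contact the distances to its \code{k} nearest
#' observed contacts (self excluded) and its \code{k_exp} nearest expected
#' contacts are collected; the signed KS statistic between the two distance
#' samples, times 100, is the contact's score. Chromosomes are scored
#' independently; trans contacts are not scored. Neighbour search uses an
#' exact kd-tree whose results equal brute-force all-pairs distances.
#'
#' @param obs Observed \code{ContactSet}.
#' @param exp \code{ExpectedContacts} (or any \code{ContactSet} serving as
#'   the null).
#' @param params \code{\link{scoring_params}}.
#' @param query Optional restriction of which cis contacts to score: either
#'   a vector of row indices into \code{obs$cis} or a loop/interval-pair
#'   data.frame (\code{chrom1,start1,end1,chrom2,start2,end2}) selecting
#'   contacts whose endpoints fall in an anchor-pair box (windows expanded
#'   by \code{query_pad} bp). Default scores every cis contact.
#' @param query_pad Padding in bp applied around query boxes (default 0).
#' @return A \code{ScoredContactSet}: the observed set with \code{score}
#'   (in [-100, 100]) and \code{D} columns on the scored rows; unscored
#'   rows carry NA when a query restriction is used.
#' @export
score_contacts <- function(obs, exp, params = scoring_params(),
                           query = NULL, query_pad = 0) {
  cis <- obs$cis
  n <- nrow(cis)
  qidx <- .resolve_query(cis, query, query_pad)
  score <- rep(NA_real_, n)
  D <- rep(NA_real_, n)
  for (ch in unique(cis$chrom[qidx])) {
    oi <- which(cis$chrom == ch)
    ei <- which(exp$cis$chrom == ch)
    if (length(oi) <= params$k)
      stop("not enough observed contacts on ", ch, " (need > k = ", params$k, ")")
    if (length(ei) < params$k_exp)
      stop("not enough expected contacts on ", ch, " (need >= k_exp = ", params$k_exp, ")")
    qi <- intersect(qidx, oi)
    res <- knn_score_cpp(cis$pos1[oi], cis$pos2[oi],
                         exp$cis$pos1[ei], exp$cis$pos2[ei],
                         match(qi, oi) - 1L, params$k, params$k_exp)
    D[qi] <- res[, 1]
    score[qi] <- 100 * res[, 2]
  }
  out <- obs
  out$cis$score <- score
  out$cis$D <- D
  out$scoring <- params
  class(out) <- unique(c("ScoredContactSet", class(obs)))
  out
}

# query -> integer indices into cis
.resolve_query <- function(cis, query, pad = 0) {
  if (is.null(query)) return(seq_len(nrow(cis)))
  if (is.numeric(query)) return(as.integer(query))
  stopifnot(is.data.frame(query))
  idx <- integer(0)
  for (r in seq_len(nrow(query))) {
    if (query$chrom1[r] != query$chrom2[r]) next
    sel <- which(cis$chrom == query$chrom1[r] &
      ((cis$pos1 >= query$start1[r] - pad & cis$pos1 <= query$end1[r] + pad &
        cis$pos2 >= query$start2[r] - pad & cis$pos2 <= query$end2[r] + pad) |
       (cis$pos1 >= query$start2[r] - pad & cis$pos1 <= query$end2[r] + pad &
        cis$pos2 >= query$start1[r] - pad & cis$pos2 <= query$end1[r] + pad)))
    idx <- c(idx, sel)
  }
  sort(unique(idx))
}

# Brute-force oracle for the kNN/KS path: all-pairs distances, no spatial
# index.  Used only by the test suite on small instances.
score_contacts_bruteforce <- function(obs, exp, params = scoring_params()) {
  cis <- obs$cis
  score <- rep(NA_real_, nrow(cis))
  D <- rep(NA_real_, nrow(cis))
  for (ch in unique(cis$chrom)) {
    oi <- which(cis$chrom == ch)
    ei <- which(exp$cis$chrom == ch)
    om <- cbind(cis$pos1[oi], cis$pos2[oi])
    em <- cbind(exp$cis$pos1[ei], exp$cis$pos2[ei])
    for (q in seq_along(oi)) {
      d_obs <- sqrt((om[, 1] - om[q, 1])^2 + (om[, 2] - om[q, 2])^2)[-q]
      d_obs <- sort(d_obs)[seq_len(params$k)]
      d_exp <- sqrt((em[, 1] - om[q, 1])^2 + (em[, 2] - om[q, 2])^2)
      d_exp <- sort(d_exp)[seq_len(params$k_exp)]
      r <- ks_d(d_obs, d_exp)
      D[oi[q]] <- r$D
      score[oi[q]] <- 100 * r$signed_D
    }
  }
  out <- obs
  out$cis$score <- score
  out$cis$D <- D
  out$scoring <- params
  class(out) <- unique(c("ScoredContactSet", class(obs)))
  out
}

#' Bin contact scores into a 2D score map
#'
#' A bin's value is the arithmetic mean of the scores of all fragment pairs
#' falling in it; bins without contacts carry no value.
#'
#' @param sc \code{ScoredContactSet}.
#' @param resolution Bin size in bp.
#' @return Object of class \code{"ScoreMap"}: per-chromosome data.frames
#'   with 0-based \code{bin1}, \code{bin2}, mean \code{score} and contact
#'   count \code{n}.
#' @export
score_map <- function(sc, resolution) {
  stopifnot(resolution > 0)
  cis <- sc$cis[!is.na(sc$cis$score), , drop = FALSE]
  maps <- lapply(split(cis, cis$chrom), function(df) {
    b1 <- floor((df$pos1 - 1) / resolution)
    b2 <- floor((df$pos2 - 1) / resolution)
    key <- paste(b1, b2)
    agg <- tapply(df$score, key, mean)
    cnt <- tapply(df$score, key, length)
    kk <- strsplit(names(agg), " ")
    data.frame(bin1 = as.integer(vapply(kk, `[`, "", 1)),
               bin2 = as.integer(vapply(kk, `[`, "", 2)),
               score = as.numeric(agg), n = as.integer(cnt))
  })
  structure(list(resolution = resolution, maps = maps), class = "ScoreMap")
}

#' Quantify contact scores between two anchor windows
#'
#' Collects the scores of every cis contact with one endpoint in
#' \code{window1} and the other in \code{window2} (fully-closed
#' containment). Shipping presets for the printed PRE windows are available
#' via \code{\link{anchor_presets}}.
#'
#' @param sc \code{ScoredContactSet}.
#' @param window1,window2 Single-row interval data.frames on the same
#'   chromosome.
#' @return List with \code{scores}, a \code{summary} vector (n, median,
#'   q25, q75) and an \code{empty} flag.
#' @export
quantify_anchor_pair <- function(sc, window1, window2) {
  stopifnot(nrow(window1) == 1L, nrow(window2) == 1L)
  if (window1$chrom != window2$chrom)
    stop("anchor windows must be cis (same chromosome)")
  q <- data.frame(chrom1 = window1$chrom, start1 = window1$start,
                  end1 = window1$end, chrom2 = window2$chrom,
                  start2 = window2$start, end2 = window2$end)
  idx <- .resolve_query(sc$cis, q)
  scores <- sc$cis$score[idx]
  scores <- scores[!is.na(scores)]
  empty <- length(scores) == 0L
  if (empty) warning("no scored contacts between the anchor windows")
  list(scores = scores,
       summary = c(n = length(scores),
                   median = if (empty) NA_real_ else median(scores),
                   q25 = if (empty) NA_real_ else unname(quantile(scores, 0.25)),
                   q75 = if (empty) NA_real_ else unname(quantile(scores, 0.75))),
       empty = empty)
}
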