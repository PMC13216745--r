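# The shuffled "expected" model: a null contact set that preserves each
# chromosome's endpoint marginals exactly (partner swaps never create or
# destroy endpoints) and its distance decay approximately, while erasing
# TADs and loops.  Built at depth_factor x the observed cis depth.

#' Shuffling parameters for the expected model
#'
#' @param depth_factor Expected cis depth as a multiple of observed
#'   (default 2).
#' @param props_per_contact Swap proposals per contact per sweep
#'   (default 10).
#' @param sweeps Number of sweeps (default 20).
#' @param decay_tolerance Target total-variation distance between the
#'   expected set's decay and the observed decay; exceeding it triggers a
#'   warning (default 0.02).
#' @param bins_per_octave Fineness of the decay grid the chain targets
#'   (default 8). The coarse doubling grid used for reporting would let
#'   the chain flatten distances within each octave, locally depressing
#'   the expected density at the short edge of every bin; a finer target
#'   grid removes that artifact.
#' @param seed RNG seed (mandatory: no implicit randomness).
#' @return List of class \code{"ShuffleParams"}.
#' @export
shuffle_params <- function(depth_factor = 2, props_per_contact = 10,
                           sweeps = 20, decay_tolerance = 0.02,
                           bins_per_octave = 8, seed) {
  if (missing(seed) || is.null(seed)) stop("shuffle seed is mandatory")
  stopifnot(depth_factor >= 1, decay_tolerance > 0, decay_tolerance < 1)
  structure(list(depth_factor = depth_factor,
                 props_per_contact = props_per_contact,
                 sweeps = sweeps, decay_tolerance = decay_tolerance,
                 bins_per_octave = bins_per_octave,
                 seed = as.integer(seed)),
            class = "ShuffleParams")
}

# Availability of each decay bin: the number of endpoint pairings whose
# separation falls in the bin, over the chromosome's observed endpoint
# multiset -- the entropy profile the swap chain drifts to under constant
# weights.  Computed exactly as the autocorrelation (via FFT) of the
# endpoint counts binned on a fine position grid, so fragment-lattice
# distance atoms and non-uniform marginals are priced without sampling
# noise; the continuous (L - s) integral misweights bins that contain only
# one or two lattice distances, and random-re-pairing estimates are too
# noisy in the narrow short-range bins.  The Metropolis weight of a bin is
# target mass / availability, making the chain's stationary distance
# histogram reproduce the target decay.
.bin_availability_fft <- function(pos1, pos2, edges, L) {
  nb <- length(edges) - 1L
  # grid finer than the narrowest bin; 25 bp for the default 200 bp floor
  g <- max(1, floor(edges[1] / 8))
  site <- as.integer(round(c(pos1, pos2) / g))
  S <- as.integer(ceiling(L / g)) + 2L
  cnt <- tabulate(site + 1L, nbins = S)
  m <- 2^ceiling(log2(2 * S))
  fa <- stats::fft(c(cnt, numeric(m - S)))
  ac <- Re(stats::fft(fa * Conj(fa), inverse = TRUE)) / m
  lag_d <- (seq_len(m %/% 2) - 1) * g     # distance of lag k = index k+1
  b <- findInterval(lag_d, edges, rightmost.closed = TRUE)
  ok <- b >= 1 & b <= nb & lag_d > 0
  A <- numeric(nb)
  acc <- tapply(ac[seq_len(m %/% 2)][ok], b[ok], sum)
  A[as.integer(names(acc))] <- pmax(acc, 0)
  A
}

#' Build the shuffled expected contact set
#'
#' Initializes with \code{depth_factor} copies of each observed cis pair
#' (already decay-exact), then runs Metropolis partner-swap sweeps per
#' chromosome: two pairs (a1,a2),(b1,b2) are exchanged to (a1,b2),(b1,a2)
#' with probability given by the ratio of decay weights of the new vs old
#' separations.  Endpoint marginals are preserved exactly by construction;
#' local structure (TADs, loops) is erased by the swaps.
#'
#' @param cs Observed \code{ContactSet} (cis records required).
#' @param params \code{\link{shuffle_params}}.
#' @param decay Optional \code{DecayCurve} estimated from \code{cs};
#'   defaults to \code{estimate_decay(cs)}.
#' @return An \code{ExpectedContacts} object: a \code{ContactSet} whose
#'   \code{provenance} field records the parameters, achieved decay TV
#'   distance and acceptance-rate trace.
#' @export
build_expected <- function(cs, params, decay = NULL) {
  if (nrow(cs$cis) == 0L) stop("no cis contacts to shuffle")
  if (is.null(decay)) decay <- estimate_decay(cs)
  # the chain targets a finer decay grid than the reporting curve, so that
  # the within-bin distance distribution of the expected set tracks the
  # observed one closely (see shuffle_params)
  fine <- estimate_decay(cs, decay_bin_edges(cs$chromsizes,
                                             min_sep = decay$edges[1],
                                             bins_per_octave = params$bins_per_octave))
  set.seed(params$seed)
  chroms <- names(cs$chromsizes)
  acc <- list()
  n_zero <- 0
  shuffled <- lapply(chroms, function(ch) {
    sel <- cs$cis$chrom == ch
    if (!any(sel)) return(NULL)
    p1 <- rep(cs$cis$pos1[sel], params$depth_factor)
    p2 <- rep(cs$cis$pos2[sel], params$depth_factor)
    mass <- fine$per_chrom[[ch]]
    if (is.null(mass)) mass <- fine$mass
    avail <- .bin_availability_fft(cs$cis$pos1[sel], cs$cis$pos2[sel],
                                   fine$edges, cs$chromsizes[[ch]])
    w <- ifelse(mass > 0 & avail > 0, mass / pmax(avail, 1e-9), 0)
    r <- shuffle_pairs_cpp(p1, p2, fine$edges, w,
                           params$sweeps, params$props_per_contact)
    acc[[ch]] <<- r$acceptance
    n_zero <<- n_zero + r$n_zero_rejected
    data.frame(chrom = ch, pos1 = r$pos1, pos2 = r$pos2,
               stringsAsFactors = FALSE)
  })
  cis <- do.call(rbind, shuffled[!vapply(shuffled, is.null, TRUE)])
  rownames(cis) <- NULL
  out <- contact_set(cis, cs$chromsizes,
                     replicate = paste0(cs$replicate, "_expected"))
  exp_decay <- estimate_decay(out, bin_edges = decay$edges)
  tv <- decay_tv_distance(decay, exp_decay)
  if (tv > params$decay_tolerance)
    warning("expected-set decay TV distance ", signif(tv, 3),
            " exceeds tolerance ", params$decay_tolerance)
  out$provenance <- list(params = params, decay_tv = tv,
                         acceptance = acc, n_zero_rejected = n_zero,
                         source_replicate = cs$replicate)
  class(out) <- c("ExpectedContacts", class(out))
  out
}

#' @export
print.ExpectedContacts <- function(x, ...) {
  cat("ExpectedContacts: ", nrow(x$cis), " cis contacts (depth factor ",
      x$provenance$params$depth_factor, "), decay TV distance ",
      signif(x$provenance$decay_tv, 3), "\n", sep = "")
  invisible(x)
}

#' Diagnostics of an expected model against its source
#'
#' @param exp \code{ExpectedContacts}.
#' @param obs Source \code{ContactSet}.
#' @param marginal_resolution Bin size for the endpoint-coverage
#'   correlation (default 10 kb).
#' @return List with the decay TV distance, the per-bin marginal coverage
#'   correlation (1 exactly, since swaps preserve endpoints), and the
#'   acceptance-rate trace per chromosome.
#' @export
shuffle_diagnostics <- function(exp, obs, marginal_resolution = 1e4) {
  stopifnot(identical(names(exp$chromsizes), names(obs$chromsizes)))
  obs_decay <- estimate_decay(obs)
  exp_decay <- estimate_decay(exp, bin_edges = obs_decay$edges)
  cover <- function(cs) {
    unlist(lapply(names(cs$chromsizes), function(ch) {
      sel <- cs$cis$chrom == ch
      pos <- c(cs$cis$pos1[sel], cs$cis$pos2[sel])
      nb <- ceiling(cs$chromsizes[[ch]] / marginal_resolution)
      tabulate(floor((pos - 1) / marginal_resolution) + 1, nbins = nb)
    }))
  }
  co <- cover(obs); ce <- cover(exp)
  structure(list(
    decay_tv = decay_tv_distance(obs_decay, exp_decay),
    marginal_correlation = if (sd(co) > 0) cor(co, ce) else NA_real_,
    acceptance = if (!is.null(exp$provenance)) exp$provenance$acceptance else NULL,
    depth_ratio = nrow(exp$cis) / nrow(obs$cis)), class = "shuffle_diagnostics")
}
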