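# Synthetic Micro-C generator.  Contacts are independent draws from an
# intensity field: power-law distance decay P(d) ~ d^-alpha (d >= min_sep),
# multiplied inside TAD blocks and inside loop anchor boxes by their
# multipliers.  Peaks, gold-standard loops and signal tracks are generated
# with the statistical couplings the downstream analysis assumes, together
# with a ground-truth manifest.

#' Define a synthetic Micro-C scenario
#'
#' The default scenario is two 5 Mb chromosomes with one TAD block each and
#' four planted loops each (eight in total) at anchor separations of
#' 40-100 kb, the scale of observed PRE-loop sizes. Strengths 6-16 are
#' chosen so that, at the default depth used for loop calling, a planted
#' loop's anchor box holds a clearly super-background Poisson count (see
#' the methods vignette for the power calculation).
#'
#' @param seed RNG seed (mandatory).
#' @param chrom_sizes Named lengths; default two chromosomes of 5 Mb.
#' @param n_contacts Total cis contacts to draw (default 2e5).
#' @param decay_exponent Power-law exponent alpha (default 1.0).
#' @param min_sep Minimum simulated separation in bp (default 200, the
#'   Micro-C proximity-filter threshold).
#' @param fragment_bp Fragment-level position granularity (default 150).
#' @param tads data.frame(chrom, start, end, multiplier) of TAD blocks.
#' @param loops data.frame(chrom, center1, center2, width, strength) of
#'   planted loops (strength is a multiplier >= 1 on the anchor box).
#' @param peak_spec List coupling peak scores to loop strength:
#'   \code{score_base}, \code{score_per_strength}, \code{score_sd},
#'   \code{fc_base}, \code{background_n}, \code{background_score} (range),
#'   \code{peak_width}.
#' @param noise Multiplicative (lognormal sd) dispersion applied to feature
#'   masses (default 0 = deterministic masses).
#' @param inject_sub200 Number of sub-200 bp pairs to inject for exercising
#'   the proximity filter (default 0).
#' @param repressive_domains Intervals of repressive chromatin for signal
#'   tracks; defaults to the TAD intervals.
#' @return List of class \code{"SyntheticScenario"}.
#' @export
synthetic_scenario <- function(seed,
                               chrom_sizes = c(chrA = 5e6, chrB = 5e6),
                               n_contacts = 2e5,
                               decay_exponent = 1.0,
                               min_sep = 200,
                               fragment_bp = 150,
                               tads = NULL,
                               loops = NULL,
                               peak_spec = NULL,
                               noise = 0,
                               inject_sub200 = 0,
                               repressive_domains = NULL) {
  if (missing(seed) || is.null(seed)) stop("scenario seed is mandatory")
  cs <- chrom_sizes(chrom_sizes)
  if (is.null(tads))
    tads <- data.frame(chrom = names(cs),
                       start = rep(2200001, length(cs)),
                       end = rep(2600000, length(cs)),
                       multiplier = 2)
  if (is.null(loops)) {
    base <- data.frame(center1 = c(601000, 1801000, 3001000, 4201000),
                       center2 = c(641000, 1861000, 3081000, 4301000),
                       width = 2000)
    # strengths arranged so every anchor box's expected extra count stays
    # well above its local Poisson background at the default calling depth
    # (extra ~ (strength - 1) x box mass, which shrinks with separation)
    loops <- rbind(cbind(chrom = names(cs)[1], base, strength = c(6, 8, 12, 16)),
                   cbind(chrom = names(cs)[min(2, length(cs))], base,
                         strength = c(8, 6, 16, 12)))
    if (length(cs) == 1) loops <- loops[1:4, ]
  }
  if (is.null(peak_spec))
    peak_spec <- list(score_base = 150, score_per_strength = 60,
                      score_sd = 15, fc_base = 3, background_n = 16,
                      background_score = c(105, 140), peak_width = 800)
  if (nrow(loops) && any(loops$strength < 1)) stop("loop strengths must be >= 1")
  if (nrow(loops)) {
    bad <- loops$center2 + loops$width / 2 > cs[loops$chrom] |
      loops$center1 - loops$width / 2 < 1
    if (any(bad)) stop("loop anchors outside chromosome")
  }
  if (is.null(repressive_domains))
    repressive_domains <- tads[, c("chrom", "start", "end")]
  structure(list(seed = as.integer(seed), chrom_sizes = cs,
                 n_contacts = n_contacts, decay_exponent = decay_exponent,
                 min_sep = min_sep, fragment_bp = fragment_bp,
                 tads = tads, loops = loops, peak_spec = peak_spec,
                 noise = noise, inject_sub200 = inject_sub200,
                 repressive_domains = repressive_domains),
            class = "SyntheticScenario")
}

# mass of the background field integral( (L-s) s^-alpha ds ) over
# [min_sep, L] -- the within-chromosome normalizer
.decay_mass_range <- function(alpha, lo, hi, L) {
  if (hi <= lo) return(0)
  s <- exp(seq(log(lo), log(hi), length.out = 4096))
  f <- (L - s) * s^(-alpha)
  sum(diff(s) * (f[-1] + f[-length(f)]) / 2)
}

# mass of a loop box [a1 +/- w/2] x [a2 +/- w/2] under s^-alpha:
# integral over u = separation of (w - |u - d|) u^-alpha
.box_mass <- function(alpha, d, w) {
  u <- seq(d - w, d + w, length.out = 512)
  u <- u[u > 0]
  f <- pmax(w - abs(u - d), 0) * u^(-alpha)
  sum(diff(u) * (f[-1] + f[-length(f)]) / 2)
}

# inverse-CDF sampler for separations with density (L - s) s^-alpha on
# [lo, hi] (hi <= L); tabulated on a log grid
.sample_decay_dist <- function(n, alpha, lo, hi, L) {
  if (n == 0) return(numeric(0))
  s <- exp(seq(log(lo), log(hi), length.out = 4096))
  f <- pmax(L - s, 0) * s^(-alpha)
  cdf <- cumsum(c(0, diff(s) * (f[-1] + f[-length(f)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  approx(cdf[keep], s[keep], xout = runif(n))$y
}

.snap <- function(pos, frag, L) {
  pmin(pmax(round(pos / frag) * frag, 1), L)
}

#' Simulate a fragment-level contact set
#'
#' Draws \code{n_contacts} independent cis contacts from the scenario's
#' intensity field and snaps positions to the fragment lattice. The
#' expected counts of every component (background per chromosome, TAD
#' extra, loop-box extra) follow the analytic masses of the field, so the
#' planted enrichment of a loop box equals its strength multiplier in
#' expectation.
#'
#' @param scenario \code{\link{synthetic_scenario}}.
#' @return List with \code{contacts} (\code{ContactSet}) and \code{truth}
#'   (ground-truth manifest: planted loops with their expected extra
#'   counts, TADs, decay parameters).
#' @export
simulate_contacts <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  if (sc$n_contacts == 0) {
    warning("n_contacts = 0: empty contact set")
    return(list(contacts = contact_set(
      data.frame(chrom = character(0), pos1 = numeric(0), pos2 = numeric(0)),
      sc$chrom_sizes), truth = list(loops = sc$loops, tads = sc$tads,
      decay = list(exponent = sc$decay_exponent, min_sep = sc$min_sep))))
  }
  alpha <- sc$decay_exponent
  chroms <- names(sc$chrom_sizes)
  comps <- list()
  for (ch in chroms) {
    L <- sc$chrom_sizes[[ch]]
    comps[[length(comps) + 1]] <- list(type = "bg", chrom = ch,
      mass = .decay_mass_range(alpha, sc$min_sep, L, L))
  }
  if (nrow(sc$tads)) for (r in seq_len(nrow(sc$tads))) {
    tad <- sc$tads[r, ]
    len <- tad$end - tad$start
    comps[[length(comps) + 1]] <- list(type = "tad", chrom = tad$chrom,
      start = tad$start, len = len,
      mass = (tad$multiplier - 1) *
        .decay_mass_range(alpha, sc$min_sep, len, len))
  }
  if (nrow(sc$loops)) for (r in seq_len(nrow(sc$loops))) {
    lp <- sc$loops[r, ]
    # a loop inside a TAD sits on the TAD-elevated background
    base_mult <- 1
    if (nrow(sc$tads)) {
      inside <- sc$tads$chrom == lp$chrom &
        sc$tads$start <= lp$center1 - lp$width / 2 &
        sc$tads$end >= lp$center2 + lp$width / 2
      if (any(inside)) base_mult <- sc$tads$multiplier[which(inside)[1]]
    }
    comps[[length(comps) + 1]] <- list(type = "loop", chrom = lp$chrom,
      loop_row = r, c1 = lp$center1, c2 = lp$center2, w = lp$width,
      mass = (lp$strength - 1) * base_mult *
        .box_mass(alpha, lp$center2 - lp$center1, lp$width))
  }
  mass <- vapply(comps, `[[`, 0, "mass")
  if (sc$noise > 0) mass <- mass * rlnorm(length(mass), 0, sc$noise)
  counts <- as.vector(rmultinom(1, sc$n_contacts, mass / sum(mass)))
  recs <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    n <- counts[i]
    if (n == 0) next
    L <- sc$chrom_sizes[[cmp$chrom]]
    if (cmp$type == "bg") {
      d <- .sample_decay_dist(n, alpha, sc$min_sep, L, L)
      x <- runif(n, 0, L - d)
      p1 <- .snap(x, sc$fragment_bp, L)
      p2 <- .snap(x + d, sc$fragment_bp, L)
    } else if (cmp$type == "tad") {
      d <- .sample_decay_dist(n, alpha, sc$min_sep, cmp$len, cmp$len)
      x <- cmp$start + runif(n, 0, cmp$len - d)
      p1 <- .snap(x, sc$fragment_bp, L)
      p2 <- .snap(x + d, sc$fragment_bp, L)
    } else {
      # near-uniform in the anchor box; thin by the decay ratio
      p1 <- p2 <- numeric(0)
      dmin_box <- cmp$c2 - cmp$c1 - cmp$w
      while (length(p1) < n) {
        m <- 2 * (n - length(p1)) + 10
        x <- runif(m, cmp$c1 - cmp$w / 2, cmp$c1 + cmp$w / 2)
        y <- runif(m, cmp$c2 - cmp$w / 2, cmp$c2 + cmp$w / 2)
        keep <- runif(m) < ((y - x) / dmin_box)^(-alpha)
        p1 <- c(p1, x[keep]); p2 <- c(p2, y[keep])
      }
      p1 <- .snap(p1[seq_len(n)], sc$fragment_bp, L)
      p2 <- .snap(p2[seq_len(n)], sc$fragment_bp, L)
    }
    # snapping can nudge a background pair below the minimum separation
    short <- p2 - p1 < sc$min_sep
    while (any(short)) {
      d <- .sample_decay_dist(sum(short), alpha, sc$min_sep, L, L)
      x <- runif(sum(short), 0, L - d)
      p1[short] <- .snap(x, sc$fragment_bp, L)
      p2[short] <- .snap(x + d, sc$fragment_bp, L)
      short <- p2 - p1 < sc$min_sep
    }
    recs[[i]] <- data.frame(chrom = cmp$chrom, pos1 = p1, pos2 = p2,
                            stringsAsFactors = FALSE)
  }
  cis <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (sc$inject_sub200 > 0) {
    ch <- sample(chroms, sc$inject_sub200, replace = TRUE)
    p1 <- floor(runif(sc$inject_sub200, 1, sc$chrom_sizes[ch] - 200))
    d <- floor(runif(sc$inject_sub200, 1, sc$min_sep))
    cis <- rbind(cis, data.frame(chrom = ch, pos1 = p1, pos2 = p1 + d,
                                 stringsAsFactors = FALSE))
  }
  rownames(cis) <- NULL
  truth_loops <- sc$loops
  if (nrow(truth_loops)) {
    li <- vapply(comps, function(c) identical(c$type, "loop"), TRUE)
    truth_loops$extra_count <- 0
    truth_loops$extra_count[vapply(comps[li], `[[`, 0L, "loop_row")] <- counts[li]
  }
  list(contacts = contact_set(cis, sc$chrom_sizes, replicate = "synthetic"),
       truth = list(loops = truth_loops, tads = sc$tads,
                    decay = list(exponent = alpha, min_sep = sc$min_sep),
                    component_counts = counts))
}

#' Simulate peaks coupled to planted loop strength
#'
#' Each planted loop anchor receives a peak whose score increases linearly
#' with the loop's strength multiplier (plus Gaussian noise); background
#' peaks are placed in pairs at 50-300 kb separations away from any anchor,
#' with scores drawn below the weakest anchor class. All generated peaks
#' pass the high-confidence filter so that quartile analyses stratify by
#' score, not by filtering.
#'
#' @param scenario \code{\link{synthetic_scenario}}.
#' @param background_only Generate only background peaks (no anchor peaks).
#' @return Peak data.frame: \code{chrom,start,end,summit,score,
#'   fold_change,loop_id,strength}.
#' @export
simulate_peaks <- function(scenario, background_only = FALSE) {
  sc <- scenario
  set.seed(sc$seed + 1L)
  ps <- sc$peak_spec
  hw <- ps$peak_width / 2
  out <- list()
  if (!background_only && nrow(sc$loops)) {
    for (r in seq_len(nrow(sc$loops))) {
      lp <- sc$loops[r, ]
      for (centre in c(lp$center1, lp$center2)) {
        score <- ps$score_base + ps$score_per_strength * lp$strength +
          rnorm(1, 0, ps$score_sd)
        out[[length(out) + 1]] <- data.frame(
          chrom = lp$chrom, start = centre - hw, end = centre + hw,
          summit = centre, score = score,
          fold_change = ps$fc_base + lp$strength / 4,
          loop_id = r, strength = lp$strength, stringsAsFactors = FALSE)
      }
    }
  }
  n_bg <- ps$background_n
  if (n_bg > 0) {
    anchors <- if (nrow(sc$loops))
      c(sc$loops$center1, sc$loops$center2) else numeric(0)
    anchor_chrom <- if (nrow(sc$loops))
      c(sc$loops$chrom, sc$loops$chrom) else character(0)
    placed <- 0
    while (placed < n_bg) {
      ch <- sample(names(sc$chrom_sizes), 1)
      L <- sc$chrom_sizes[[ch]]
      sep <- runif(1, 5e4, 3e5)
      c1 <- runif(1, 1e4, L - sep - 1e4)
      c2 <- c1 + sep
      near <- anchor_chrom == ch &
        (abs(anchors - c1) < 2e4 | abs(anchors - c2) < 2e4)
      if (any(near)) next
      for (centre in c(c1, c2)[seq_len(min(2, n_bg - placed))]) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = round(centre) - hw, end = round(centre) + hw,
          summit = round(centre),
          score = runif(1, ps$background_score[1], ps$background_score[2]),
          fold_change = runif(1, 2.1, 3),
          loop_id = NA_integer_, strength = NA_real_, stringsAsFactors = FALSE)
        placed <- placed + 1
      }
    }
  }
  pk <- do.call(rbind, out)
  rownames(pk) <- NULL
  pk
}

#' Simulate block-structured signal tracks
#'
#' Produces three bedGraph-style tracks: a repressive-mark-like track high
#' across the scenario's repressive domains, an active-mark-like track high
#' elsewhere, and a flat accessibility-like track, each with additive
#' Gaussian noise.
#'
#' @param scenario \code{\link{synthetic_scenario}}.
#' @param bin_bp Track bin size (default 500).
#' @return Named list of interval data.frames with a \code{value} column
#'   (\code{repressive}, \code{active}, \code{accessibility}).
#' @export
simulate_signal_tracks <- function(scenario, bin_bp = 500) {
  sc <- scenario
  set.seed(sc$seed + 2L)
  mk_track <- function(level_in, level_out, sd) {
    do.call(rbind, lapply(names(sc$chrom_sizes), function(ch) {
      L <- sc$chrom_sizes[[ch]]
      starts <- seq(1, L, by = bin_bp)
      ends <- pmin(starts + bin_bp - 1, L)
      mid <- (starts + ends) / 2
      dom <- sc$repressive_domains[sc$repressive_domains$chrom == ch, , drop = FALSE]
      inside <- rep(FALSE, length(mid))
      for (r in seq_len(nrow(dom)))
        inside <- inside | (mid >= dom$start[r] & mid <= dom$end[r])
      data.frame(chrom = ch, start = starts, end = ends,
                 value = ifelse(inside, level_in, level_out) +
                   rnorm(length(mid), 0, sd),
                 stringsAsFactors = FALSE)
    }))
  }
  list(repressive = mk_track(6, 0.5, 0.4),
       active = mk_track(0.5, 4, 0.4),
       accessibility = mk_track(2, 2, 0.4))
}

#' Gold-standard loop records from a scenario's planted loops
#'
#' A synthetic stand-in for a manually curated loop list: the selected
#' planted loops as BEDPE-style records with anchors of +/- \code{halo} bp
#' around the true centers. The default takes every planted loop, emulating
#' a complete curated catalogue; pass \code{which} for a partial one.
#'
#' @param scenario \code{\link{synthetic_scenario}}.
#' @param which Row indices of planted loops to include (default: all).
#' @param halo Anchor half-width in bp (default 1000).
#' @return Loop data.frame.
#' @export
gold_standard_from_truth <- function(scenario, which = NULL, halo = 1000) {
  lp <- scenario$loops
  if (is.null(which)) which <- seq_len(nrow(lp))
  lp <- lp[which, , drop = FALSE]
  data.frame(chrom1 = lp$chrom, start1 = lp$center1 - halo,
             end1 = lp$center1 + halo,
             chrom2 = lp$chrom, start2 = lp$center2 - halo,
             end2 = lp$center2 + halo,
             name = paste0("gold_", seq_len(nrow(lp))),
             trans = FALSE, stringsAsFactors = FALSE)
}

#' Scenario coupling peak scores to planted loop strength
#'
#' The quartile-recovery study condition: three loop-strength classes (3,
#' 6, 12) of eight loops each, interleaved along two 5 Mb chromosomes so
#' that same-class loops are >500 kb apart (within-quartile feature pairs
#' then contain exactly the planted anchor pairs), plus 16 non-looping
#' background peaks. Anchor peak scores increase with strength class, so
#' score quartiles Q2-Q4 map to the three classes and Q1 to background.
#'
#' @param seed RNG seed.
#' @param n_contacts Total cis contacts (default 1.5e6; see the methods
#'   vignette for the supporting power calculation).
#' @return A \code{\link{synthetic_scenario}}.
#' @export
coupled_peak_scenario <- function(seed, n_contacts = 1.5e6) {
  seps <- c(40000, 60000, 80000, 100000)
  strengths <- rep(c(3, 6, 12), 4)
  mk <- function(ch) {
    c1 <- 400000 * seq_len(12) - 200000 + 1000
    data.frame(chrom = ch, center1 = c1, center2 = c1 + seps[(seq_len(12) - 1) %% 4 + 1],
               width = 2000, strength = strengths)
  }
  synthetic_scenario(seed = seed,
                     n_contacts = n_contacts,
                     tads = data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0), multiplier = numeric(0)),
                     loops = rbind(mk("chrA"), mk("chrB")),
                     peak_spec = list(score_base = 150, score_per_strength = 60,
                                      score_sd = 15, fc_base = 3,
                                      background_n = 16,
                                      background_score = c(105, 140),
                                      peak_width = 800))
}
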