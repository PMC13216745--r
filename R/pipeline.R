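# Config-driven end-to-end orchestration of the synthetic demonstration
# pipeline: simulate -> filter -> expected -> score -> aggregate ->
# call loops -> quantify -> cluster, with per-stage seeds derived from one
# global seed and a manifest of parameters and stage fingerprints.

#' Run the full pipeline on a synthetic scenario
#'
#' Every stochastic stage receives an explicit seed derived from
#' \code{config$seed}; rerunning with the same config reproduces the
#' manifest fingerprints exactly.
#'
#' @param config List with at least \code{seed}; optional entries:
#'   \code{scenario} (a \code{\link{synthetic_scenario}}; default built
#'   from the derived seed), \code{shuffle} (\code{\link{shuffle_params}}
#'   overrides), \code{scoring} (\code{\link{scoring_params}}),
#'   \code{loop_call} (\code{\link{loop_call_params}}), \code{aggregate}
#'   (list with \code{w}, \code{resolution}), \code{kmeans} (list with
#'   \code{k}, \code{flank}, \code{n_bins}), \code{out_dir} (write
#'   artifacts as text files when set).
#' @return List of stage artifacts plus a \code{manifest} recording seeds,
#'   parameters and numeric fingerprints per stage.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  seed <- as.integer(config$seed)
  scenario <- config$scenario
  if (is.null(scenario)) scenario <- synthetic_scenario(seed = seed)
  manifest <- list(seed = seed, scenario_seed = scenario$seed)
  sim <- simulate_contacts(scenario)
  obs <- filter_min_distance(sim$contacts, scenario$min_sep)
  manifest$simulate <- c(n_cis = nrow(obs$cis),
                         n_filtered = attr(obs, "n_removed"),
                         sum_pos = sum(obs$cis$pos1) %% 1e9)
  sp <- config$shuffle
  if (is.null(sp)) sp <- shuffle_params(seed = seed + 1L)
  exp <- build_expected(obs, sp)
  manifest$expected <- c(depth_ratio = nrow(exp$cis) / nrow(obs$cis),
                         decay_tv = exp$provenance$decay_tv)
  peaks <- simulate_peaks(scenario)
  peaks <- assign_quartiles(filter_high_confidence(peaks))
  agg_cfg <- config$aggregate
  if (is.null(agg_cfg)) agg_cfg <- list(w = 2e4, resolution = 250)
  report <- quartile_aggregate_report(peaks, obs, exp,
                                      w = agg_cfg$w,
                                      resolution = agg_cfg$resolution)
  manifest$aggregate <- report$central_mean
  gold <- gold_standard_from_truth(scenario)
  lp <- config$loop_call
  if (is.null(lp))
    lp <- loop_call_params(schedule = data.frame(
      resolution = c(2000, 4000), d_min = 1e4, d_max = c(4e5, 8e5)))
  loops <- call_loops(obs, exp, gold, lp, score_resolution = 400)
  manifest$loops <- c(n_loops = nrow(loops),
                      n_masked = attr(loops, "n_removed"))
  quant <- NULL
  if (nrow(scenario$loops)) {
    l1 <- scenario$loops[1, ]
    w1 <- gintervals(l1$chrom, l1$center1 - 3000, l1$center1 + 3000)
    w2 <- gintervals(l1$chrom, l1$center2 - 3000, l1$center2 + 3000)
    sc <- score_contacts(obs, exp, config$scoring %||% scoring_params(),
                         query = data.frame(chrom1 = w1$chrom,
                                            start1 = w1$start, end1 = w1$end,
                                            chrom2 = w2$chrom,
                                            start2 = w2$start, end2 = w2$end))
    quant <- quantify_anchor_pair(sc, w1, w2)
    manifest$quantify <- quant$summary
  }
  tracks <- simulate_signal_tracks(scenario)
  km_cfg <- config$kmeans
  if (is.null(km_cfg)) km_cfg <- list(k = 2, flank = 1e4, n_bins = 20)
  sm <- cbind(
    extract_signal_matrix(tracks$repressive, peaks, km_cfg$flank,
                          km_cfg$n_bins, scenario$chrom_sizes),
    extract_signal_matrix(tracks$active, peaks, km_cfg$flank,
                          km_cfg$n_bins, scenario$chrom_sizes))
  km <- kmeans_signal(sm, km_cfg$k, seed = seed + 2L,
                      first_track_cols = seq_len(km_cfg$n_bins))
  manifest$cluster <- c(sizes = km$sizes)
  out <- list(observed = obs, expected = exp, peaks = peaks,
              aggregate = report, loops = loops, quantify = quant,
              kmeans = km, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pairs(obs, file.path(config$out_dir, "observed.pairs"))
    write_pairs(exp, file.path(config$out_dir, "expected.pairs"))
    write_loops(loops, file.path(config$out_dir, "loops.bedpe"))
    dput(manifest, file.path(config$out_dir, "manifest.txt"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
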