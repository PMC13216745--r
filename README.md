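# preloop

Contact-map analysis of chromatin loops at Polycomb response elements
(PREs) and other paired regulatory features, for Micro-C and Hi-C data.
The package is aimed at chromatin biologists and computational
genomicists who have fragment-level ligation pairs (4DN-style pairs
text) and want quantitative, null-calibrated statements about loops:
how enriched a contact is over a distance-decay null, whether pairs of
transcription-factor peaks loop more as occupancy grows, where loops
are, and how loop strength changes between conditions.

## What it computes

**Shuffled expected model.** The null ("expected") contact set is
built per chromosome by Metropolis partner swaps at 2x observed cis
depth: two pairs (a1,a2), (b1,b2) are re-matched to (a1,b2), (b1,a2)
(or the alternative pairing) with acceptance probability

    min(1, w(d'1) w(d'2) / w(d1) w(d2)),   w(b) = m(b) / A(b)

where m(b) is the observed decay mass of distance bin b and A(b) the
bin's pairing availability (estimated by random re-pairing of the
observed endpoints). Endpoint marginals are preserved exactly — swaps
never create endpoints — and the distance-decay histogram is preserved
to a total-variation distance below 0.02, while TADs and loops are
erased.

**Contact scores.** Each observed cis contact *i* is scored by the
signed two-sample Kolmogorov–Smirnov statistic between the 2D
distances to its k = 250 nearest observed and k_exp = 500 nearest
expected contacts:

    score_i = 100 * ( F_obs(d*) - F_exp(d*) ),   d* = argmax |F_obs - F_exp|

on a −100..+100 scale; positive means local contact enrichment over
the null. Score maps average the scores of the fragment pairs in each
bin; anchor-pair quantification pools the scores of all contacts
between two windows (e.g. the 6 kb PRE windows shipped in
`anchor_presets()`) and summarizes them by median and quartiles.

**Aggregate (APA) enrichment.** Pairs of peaks with centre separations
in [10 kb, 500 kb] are pooled into w x w windows (w = 20 kb for peaks,
8 kb for loops) at 250 bp resolution; enrichment is
log2((O + 1)/(E' + 1)) with the expected counts depth-corrected, and
the central 8 x 8 square is compared across peak-score quartiles with
Kruskal–Wallis plus Dunn's post hoc test (Benjamini–Hochberg).

**Loop calling.** Balanced (ICE) matrices at a schedule of resolutions
are scanned by a scale-space detector (Gaussian scales sigma =
0.6–3.6 by 0.1; strict 3x3 local maxima persisting at >= 2 scales;
Poisson p-values against a donut background; BH per resolution). The
per-resolution FDR threshold is calibrated against a gold-standard
loop set by maximizing r_GS = gold detected / total detected over
thresholds 0.0001–0.1 (step 0.0001); calls are merged within and
across resolutions, pericentromeric regions are masked, and each loop
is recentered on its contact-score summit +/- 2 kb.

**Synthetic Micro-C.** `synthetic_scenario()` / `simulate_contacts()`
generate contact sets with power-law decay (d^-1), TAD blocks, planted
loops of tunable strength at 40–100 kb separations, peaks whose scores
track loop strength, and block-structured signal tracks — with a
ground-truth manifest, so the full pipeline is testable without any
sequencing download.

## Worked example

Simulate the default two-chromosome scenario with eight planted loops,
build the expected model, call loops against the planted gold standard,
and quantify one anchor pair:

```r
library(preloop)

sc   <- synthetic_scenario(seed = 777, n_contacts = 3e6)
sim  <- simulate_contacts(sc)
obs  <- filter_min_distance(sim$contacts)        # drop < 200 bp pairs
exp  <- build_expected(obs, shuffle_params(seed = 778))
exp
#> ExpectedContacts: 6000000 cis contacts (depth factor 2),
#>   decay TV distance 0.00253

gold  <- gold_standard_from_truth(sc)
loops <- call_loops(obs, exp, gold,
                    loop_call_params(schedule = data.frame(
                      resolution = c(2000, 4000),
                      d_min = 1e4, d_max = c(4e5, 8e5))))
loops
#> LoopSet with 7 loop(s)
```

Seven of the eight planted loops are recovered with no false
positives (one weak loop's draw falls behind the calibrated
per-resolution threshold); every call is recentered onto its contact
score summit, landing within one bin of the planted anchor centres
(e.g. the first call's anchors become chrA:598,200-602,200 x
chrA:639,800-643,800 around the planted centres 601,000/641,000).
The per-resolution calibration reports are in
`attr(loops, "calibration")`; the selected FDR thresholds for this
run were 0.0023 (2 kb) and 0.0028 (4 kb).

Scoring an anchor pair (here the strongest chrA loop at 100 kb
separation, via a restricted query so only the window contacts are
scored):

```r
w1 <- gintervals("chrA", 4198000, 4204000)
w2 <- gintervals("chrA", 4298000, 4304000)
sq <- score_contacts(obs, exp, query = data.frame(
  chrom1 = "chrA", start1 = w1$start, end1 = w1$end,
  chrom2 = "chrA", start2 = w2$start, end2 = w2$end))
quantify_anchor_pair(sq, w1, w2)$summary
#>      n median    q25    q75
#>     29      8      7      9
```

The 29 window contacts score consistently positive (median +8, IQR
7-9) against a null-pair median near 0. The score magnitude grows as
sequencing concentrates on a locus: in the package's zoomed
single-locus condition (1.5 Mb, 6e5 contacts) the anchor-pair median
rises to ~+70 for a strength-8 loop and decreases strictly through
~+48, ~+17 to ~-7 across planted strengths 8/4/2/1 -- the
mutant-series gradient the statistics layer compares with
Kruskal-Wallis/Dunn.

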