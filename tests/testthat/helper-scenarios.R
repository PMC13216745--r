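# shared scenario builders for the test suite

# decay-only scenario: no TADs, no loops
plain_scenario <- function(seed, n = 1e4, chroms = c(chrA = 5e6), ...) {
  synthetic_scenario(
    seed = seed, chrom_sizes = chroms, n_contacts = n,
    tads = data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), multiplier = numeric(0)),
    loops = data.frame(chrom = character(0), center1 = numeric(0),
                       center2 = numeric(0), width = numeric(0),
                       strength = numeric(0)),
    ...)
}

# one planted loop on a single 5 Mb chromosome
one_loop_scenario <- function(seed, strength, n = 3e5, width = 6000,
                              c1 = 2501000, c2 = 2561000) {
  synthetic_scenario(
    seed = seed, chrom_sizes = c(chrA = 5e6), n_contacts = n,
    tads = data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), multiplier = numeric(0)),
    loops = data.frame(chrom = "chrA", center1 = c1, center2 = c2,
                       width = width, strength = strength))
}

# hand-built contact set from explicit positions
tiny_contacts <- function(pos1, pos2, chrom = "chrA", L = 5e6) {
  contact_set(data.frame(chrom = chrom, pos1 = pos1, pos2 = pos2),
              chrom_sizes(setNames(L, unique(chrom))))
}

# count contacts inside a loop box
box_count <- function(cs, chrom, c1, c2, half) {
  sum(cs$cis$chrom == chrom &
        abs(cs$cis$pos1 - c1) <= half & abs(cs$cis$pos2 - c2) <= half)
}
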