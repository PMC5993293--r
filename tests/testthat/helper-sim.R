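# shared fixtures, all generated in code

# tiny deterministic genome: one chromosome of the given length
tiny_sizes <- function(len = 1000L, chroms = "chr1") {
  setNames(rep(len, length(chroms)), chroms)
}

# width-1 stranded tags at 1-based positions
make_tags <- function(pos, strand = "+", chrom = "chr1", weight = 1) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               strand = strand)
  gr$weight <- rep_len(weight, length(gr))
  gr
}

gr_ivl <- function(start1, end1, chrom = "chr1", strand = "*") {
  GenomicRanges::GRanges(rep_len(chrom, length(start1)),
                         IRanges::IRanges(start1, end1),
                         strand = rep_len(strand, length(start1)))
}

# a constant-value track over given chromosome sizes
flat_track <- function(sizes, value = 1) {
  cut_track(lapply(sizes, function(L) rep(value, L)))
}

# exact cleavage-bias oracle from the generator's own hexamer factors:
# expected rate per context inside open chromatin
oracle_bias <- function(sim) {
  cfg <- sim$config
  structure(list(rate = sim$hexamer_factors * cfg$base_rate * cfg$access_bump,
                 mean_rate = cfg$base_rate * cfg$access_bump,
                 context_counts = rep(1, 4096), pseudocount = 0),
            class = "hexamer_bias")
}

# small simulated study used across test files
small_sim <- function(seed = 5, ...) {
  simulate_genome(sim_config(seed = seed, chrom_lengths = c(chr1 = 3e5),
                             n_promoters = 80, n_enhancers = 15, ...))
}
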