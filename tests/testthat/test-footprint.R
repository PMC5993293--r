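test_that("uniform cutting learns equal rates for every context", {
  sim <- small_sim()
  uni <- flat_track(sim$sizes, 2.0)
  bias <- learn_hexamer_bias(uni, sim$dhs, sim$genome)
  seen <- bias$context_counts > 0
  expect_true(all(abs(bias$rate[seen] - 2.0) < 1e-12))
  expect_equal(bias$mean_rate, 2.0)
  expect_true(all(bias$rate > 0))
  expect_error(learn_hexamer_bias(uni, sim$dhs,
                                  Biostrings::DNAStringSet(c(chr1 = ""))),
               "empty")
})

test_that("a planted 2:1 context bias is recovered within 5%", {
  set.seed(9)
  sizes <- tiny_sizes(200000)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE),
                collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1))
  codes <- accessilate:::.hexamer_codes(accessilate:::.base_codes(genome[[1]]))
  # contexts whose first two bases are GC cut at twice the rate
  gc_first <- !is.na(codes) & floor(codes / 256) == 9  # G=2,C=1 -> 2*4+1
  rate <- ifelse(gc_first, 2, 1) * 0.5
  rate[is.na(codes)] <- 0.5
  trk <- cut_track(list(chr1 = rpois(200000, rate)))
  dhs <- gr_ivl(1, 200000)
  bias <- learn_hexamer_bias(trk, dhs, genome, pseudocount = 0.01)
  idx_gc <- which(floor(0:4095 / 256) == 9)
  ratio <- mean(bias$rate[idx_gc]) / mean(bias$rate[-idx_gc])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("dividing a track by its own learned expectations averages to 1", {
  sim <- small_sim(seed = 13, base_rate = 1)
  trk <- simulate_cut_track(sim, "control", occupancy = 0)
  bias <- learn_hexamer_bias(trk, sim$dhs, sim$genome, pseudocount = 1e-12)
  red <- GenomicRanges::reduce(sim$dhs)
  codes <- accessilate:::.hexamer_codes(accessilate:::.base_codes(sim$genome[[1]]))
  cov <- as.numeric(trk$cov$chr1)
  pos <- unlist(mapply(seq, GenomicRanges::start(red), GenomicRanges::end(red)))
  pos <- pos[!is.na(codes[pos])]
  ratio <- cov[pos] / bias$rate[codes[pos] + 1]
  expect_equal(mean(ratio), 1, tolerance = 1e-6)
})

test_that("a single instance on a uniform, unbiased track gives ratio 1", {
  sizes <- tiny_sizes(4000)
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")))
  uni <- flat_track(sizes, 3)
  bias <- structure(list(rate = rep(3, 4096), mean_rate = 3,
                         context_counts = rep(1, 4096), pseudocount = 0),
                    class = "hexamer_bias")
  inst <- gr_ivl(2000, 2009, strand = "+")
  prof <- footprint_profile(uni, inst, bias, genome, flank = 50)
  expect_equal(prof$ratio, rep(1, 110))
  expect_equal(prof$position, seq(-50, 59))
})

test_that("half occupancy suppressing central cuts by half gives r ~ 0.75", {
  # expected central ratio is the mixture 0.5*1 + 0.5*0.5 = 0.75 when the
  # expected rates are the generator's own (no learning noise)
  sim <- small_sim(seed = 17, base_rate = 1, frac_bound = 1,
                   protection_depth = 0.5)
  trk <- simulate_cut_track(sim, "control", occupancy = 0.5)
  prof <- footprint_profile(trk, sim$motifs, oracle_bias(sim), sim$genome,
                            flank = 50)
  centre <- floor(nchar(sim$config$motif_consensus) / 2)
  central <- prof$position >= centre - 5 & prof$position <= centre + 4
  flankpos <- abs(prof$position - centre) >= 21
  expect_equal(mean(prof$ratio[central]), 0.75, tolerance = 0.05)
  expect_equal(mean(prof$ratio[flankpos]), 1.0, tolerance = 0.05)
})

test_that("profiles flip coordinates when all instance strands flip", {
  sim <- small_sim(seed = 19, base_rate = 0.5)
  trk <- simulate_cut_track(sim, "control")
  bias <- learn_hexamer_bias(trk, sim$dhs, sim$genome)
  prof <- footprint_profile(trk, sim$motifs, bias, sim$genome, flank = 30)
  flipped <- sim$motifs
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(sim$motifs)) == "+", "-", "+")
  prof2 <- footprint_profile(trk, flipped, bias, sim$genome, flank = 30)
  expect_equal(prof2$ratio, rev(prof$ratio), tolerance = 1e-12)
})

test_that("footprint magnitude is the centre-minus-background difference", {
  mk_prof <- function(r) structure(
    list(position = seq(-50, 59), ratio = r, n_instances = 4,
         motif_width = 10, flank = 50,
         obs = matrix(rep(r, each = 4), 4), expected = matrix(1, 4, 110)),
    class = "footprint_profile")
  expect_equal(footprint_magnitude(mk_prof(rep(1, 110)))$magnitude, 0)
  centre_idx <- 50 + 5 + 1
  r <- rep(1, 110)
  d <- abs(seq_len(110) - centre_idx)
  r[(centre_idx - 5):(centre_idx + 4)] <- 0.6
  expect_equal(footprint_magnitude(mk_prof(r))$magnitude, -0.4)
  expect_error(footprint_magnitude(mk_prof(r), background = c(3, 50)),
               "overlaps the central window")
  expect_error(footprint_magnitude(mk_prof(r), background = c(21, 500)),
               "flank too narrow")
})

test_that("identical conditions give delta-M near zero; occupancy orders |M|", {
  sim <- small_sim(seed = 23, base_rate = 1, frac_bound = 1)
  trk <- simulate_cut_track(sim, "control", occupancy = 0.6)
  bias <- learn_hexamer_bias(trk, sim$dhs, sim$genome)
  prof <- footprint_profile(trk, sim$motifs, bias, sim$genome, flank = 50)
  cmp_same <- compare_footprints(prof, prof, n_boot = 100, seed = 4)
  expect_equal(cmp_same$delta_m, 0)

  lo <- simulate_cut_track(sim, "knockdown", occupancy = 0.2, seed = 81)
  hi <- simulate_cut_track(sim, "control", occupancy = 0.8, seed = 82)
  p_lo <- footprint_profile(lo, sim$motifs,
                            learn_hexamer_bias(lo, sim$dhs, sim$genome),
                            sim$genome, flank = 50)
  p_hi <- footprint_profile(hi, sim$motifs,
                            learn_hexamer_bias(hi, sim$dhs, sim$genome),
                            sim$genome, flank = 50)
  m_lo <- footprint_magnitude(p_lo)$magnitude
  m_hi <- footprint_magnitude(p_hi)$magnitude
  expect_gt(abs(m_hi), abs(m_lo))
  cmp <- compare_footprints(p_hi, p_lo, n_boot = 100, seed = 4)
  expect_lt(cmp$delta_m, 0)
  expect_gt(cmp$se_boot, 0)

  # zero occupancy: magnitude indistinguishable from zero
  none <- simulate_cut_track(sim, "knockdown", occupancy = 0, seed = 83)
  p_none <- footprint_profile(none, sim$motifs,
                              learn_hexamer_bias(none, sim$dhs, sim$genome),
                              sim$genome, flank = 50)
  m_none <- footprint_magnitude(p_none)
  expect_lt(abs(m_none$magnitude), 5 * m_none$se + 0.02)
})

test_that("profiles with mismatched geometry are rejected", {
  sim <- small_sim(seed = 29)
  trk <- simulate_cut_track(sim, "control")
  bias <- learn_hexamer_bias(trk, sim$dhs, sim$genome)
  p30 <- footprint_profile(trk, sim$motifs, bias, sim$genome, flank = 30)
  p50 <- footprint_profile(trk, sim$motifs, bias, sim$genome, flank = 50)
  expect_error(compare_footprints(p30, p50), "flank")
})
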