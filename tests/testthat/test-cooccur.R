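test_that("overlap counting honours slop and half-open boundaries", {
  sizes <- tiny_sizes(10000)
  # 0-based query [100,200), reference [600,700), slop 500: expanded
  # reference [100,1200) touches the query
  q <- gr_ivl(101, 200)
  r <- gr_ivl(601, 700)
  expect_equal(count_overlaps_slop(q, r, 500, sizes), 1L)
  expect_equal(count_overlaps_slop(q, r, 0, sizes), 0L)
  # boundary: expanded reference starting exactly at query end: no overlap
  expect_equal(count_overlaps_slop(gr_ivl(1, 100), gr_ivl(601, 700), 500,
                                   sizes), 0L)
  expect_error(count_overlaps_slop(q, r, -1, sizes), "non-negative")
  # identical sets, slop 0: k = n
  set.seed(5)
  s <- sample(9000, 20)
  idn <- gr_ivl(s, s + 50)
  expect_equal(count_overlaps_slop(idn, idn, 0, sizes), 20L)
})

test_that("fast overlap counting matches the quadratic oracle", {
  set.seed(13)
  sizes <- tiny_sizes(50000, c("chr1", "chr2"))
  for (rep in 1:5) {
    qs <- sample(49000, 30)
    rs <- sample(49000, 25)
    q <- GenomicRanges::GRanges(sample(names(sizes), 30, TRUE),
                                IRanges::IRanges(qs, qs + sample(500, 30, TRUE)))
    r <- GenomicRanges::GRanges(sample(names(sizes), 25, TRUE),
                                IRanges::IRanges(rs, rs + sample(500, 25, TRUE)))
    slop <- sample(c(0, 100, 500), 1)
    brute <- sum(vapply(seq_along(q), function(i) {
      any(as.character(GenomicRanges::seqnames(r)) ==
            as.character(GenomicRanges::seqnames(q))[i] &
          pmax(GenomicRanges::start(r) - slop, 1) <= GenomicRanges::end(q)[i] &
          pmin(GenomicRanges::end(r) + slop, 50000) >= GenomicRanges::start(q)[i])
    }, logical(1)))
    expect_equal(count_overlaps_slop(q, r, slop, sizes), brute)
  }
})

test_that("binomial overlap tail matches closed forms and direct summation", {
  sizes <- tiny_sizes(1000)
  half <- gr_ivl(1, 500)                     # p_chance 0.5
  res <- binomial_overlap_test(2, 2, half, 0, sizes)
  expect_equal(res$p_chance, 0.5)
  expect_equal(res$binomial_p, 0.25)
  expect_equal(binomial_overlap_test(0, 2, half, 0, sizes)$binomial_p, 1.0)
  # n 20, p 0.1, k 6 against exhaustive summation
  tenth <- gr_ivl(1, 100)
  direct <- sum(vapply(6:20, function(i)
    choose(20, i) * 0.1^i * 0.9^(20 - i), numeric(1)))
  expect_equal(binomial_overlap_test(6, 20, tenth, 0, sizes)$binomial_p,
               direct, tolerance = 1e-12)
  # nested references are merged before computing coverage
  nested <- c(gr_ivl(1, 500), gr_ivl(100, 300))
  expect_equal(binomial_overlap_test(1, 1, nested, 0, sizes)$p_chance, 0.5)
  # degenerate full coverage
  expect_equal(binomial_overlap_test(3, 3, gr_ivl(1, 1000), 0,
                                     sizes)$binomial_p, 1)
})

test_that("gap-retaining randomization preserves width and gap multisets", {
  sizes <- tiny_sizes(100000, c("chr1", "chr2"))
  set.seed(3)
  mk_peaks <- function() {
    s <- sort(sample(90000, 15))
    GenomicRanges::GRanges(sample(names(sizes), 15, TRUE),
                           IRanges::IRanges(s, width = sample(50:500, 15)))
  }
  gap_multiset <- function(gr, L) {
    out <- list()
    for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      g <- sort(g)
      s0 <- GenomicRanges::start(g) - 1
      e0 <- s0 + GenomicRanges::width(g)
      n <- length(g)
      gaps <- if (n == 1) L - GenomicRanges::width(g) else
        c(s0[-1] - e0[-n], L - e0[n] + s0[1])
      out[[ch]] <- list(w = sort(GenomicRanges::width(g)), g = sort(gaps))
    }
    out[order(names(out))]
  }
  for (i in 1:5) {
    pk <- mk_peaks()
    rnd <- randomize_retaining_gaps(pk, sizes, seed = 100 + i)
    expect_equal(gap_multiset(rnd, 100000), gap_multiset(pk, 100000))
    # repeated application still preserves the multisets
    rnd2 <- randomize_retaining_gaps(rnd, sizes, seed = 200 + i)
    expect_equal(gap_multiset(rnd2, 100000), gap_multiset(pk, 100000))
  }
  # determinism under a fixed seed
  pk <- mk_peaks()
  a <- randomize_retaining_gaps(pk, sizes, seed = 9)
  b <- randomize_retaining_gaps(pk, sizes, seed = 9)
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  # single peak: width preserved, position moved somewhere valid
  one <- gr_ivl(500, 999)
  r1 <- randomize_retaining_gaps(one, tiny_sizes(10000), seed = 2)
  expect_equal(GenomicRanges::width(r1), 500)
  expect_lte(GenomicRanges::end(r1), 10000)
})

test_that("empirical overlap P has the advertised bounds and manifest count", {
  sizes <- tiny_sizes(1000000)
  set.seed(8)
  s <- sort(sample(990000, 12))
  q <- gr_ivl(s, s + 49)
  # reference covering the whole genome: every randomization hits k = n
  all_ref <- gr_ivl(1, 1000000)
  res <- empirical_overlap_test(q, all_ref, 0, sizes, n_rand = 99, seed = 1)
  expect_equal(res$empirical_p, 1)
  expect_equal(res$n_rand, 99)
  # strongly co-located sets: empirical P at its minimum 1/(n_rand + 1)
  res2 <- empirical_overlap_test(q, q, 0, sizes, n_rand = 99, seed = 1)
  expect_equal(res2$empirical_p, 1 / 100)
  expect_equal(res2$k, 12)
})

test_that("empirical and binomial P agree in order of magnitude", {
  cfg <- sim_config(seed = 31, chrom_lengths = c(chr1 = 1e6),
                    n_peaks = 60L, peak_width = 300L)
  pp <- simulate_peak_pair(cfg, rho = 0.3)
  res <- empirical_overlap_test(pp$b, pp$a, slop = 200, genome = pp$sizes,
                                n_rand = 400, seed = 5)
  if (res$binomial_p > 1e-3) {
    expect_lt(abs(log10(res$empirical_p) - log10(res$binomial_p)), 1)
  } else {
    expect_lt(res$empirical_p, 0.05)
  }
})

test_that("phi2 equals squared Pearson correlation of the indicators", {
  # identical non-constant vectors
  v <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  co <- coassociation(v, v)
  expect_equal(co$phi2, 1)
  expect_equal(co$jaccard, 1)
  # a=4, b=1, c=1, d=4: phi2 = 225/625
  A <- rep(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1, 4))
  B <- rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1, 4))
  expect_equal(coassociation(A, B)$phi2, 0.36)
  # balanced independence: phi2 = 0
  A2 <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 5)
  B2 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 5)
  expect_equal(coassociation(A2, B2)$phi2, 0)
  # table formula vs squared Pearson on random instances, 1e-12
  set.seed(17)
  for (i in 1:20) {
    a <- runif(50) < runif(1, 0.2, 0.8)
    b <- runif(50) < runif(1, 0.2, 0.8)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(coassociation(a, b)$phi2, cor(a, b)^2, tolerance = 1e-12)
  }
  expect_warning(co0 <- coassociation(rep(TRUE, 5), v), "constant")
  expect_true(is.nan(co0$phi2))
})

test_that("datasets rank by phi2 with jaccard then name as tie-breaks", {
  ref <- rep(c(TRUE, FALSE), each = 10)
  strong <- ref
  weak <- c(ref[-1], TRUE)
  none <- rep(c(TRUE, FALSE), 10)
  rk <- coassociation_rank(list(zzz = weak, strong = strong, none = none), ref)
  expect_equal(rk$dataset, c("strong", "zzz", "none"))
  expect_equal(rk$rank, 1:3)
  # exact phi2 ties resolve by name
  rk2 <- coassociation_rank(list(b = strong, a = strong), ref)
  expect_equal(rk2$dataset, c("a", "b"))
})
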