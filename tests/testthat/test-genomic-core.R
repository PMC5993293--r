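test_that("fragments extend 3'-ward from the tag start on each strand", {
  sizes <- tiny_sizes(1000)
  # 0-based tag 100 = 1-based 101; expect 0-based [100, 400)
  plus <- extend_fragments(make_tags(101, "+"), 300, sizes)
  expect_equal(GenomicRanges::start(plus), 101)
  expect_equal(GenomicRanges::end(plus), 400)
  # 0-based minus tag 499 = 1-based 500; expect 0-based [200, 500)
  minus <- extend_fragments(make_tags(500, "-"), 300, sizes)
  expect_equal(GenomicRanges::start(minus), 201)
  expect_equal(GenomicRanges::end(minus), 500)
  # 1 bp extension identifies the individual cut site
  cut <- extend_fragments(make_tags(101, "+"), 1, sizes)
  expect_equal(GenomicRanges::width(cut), 1)
  expect_equal(GenomicRanges::start(cut), 101)
})

test_that("extension clips at chromosome edges and keeps weights", {
  sizes <- tiny_sizes(1000)
  near_end <- extend_fragments(make_tags(901, "+", weight = 0.2), 300, sizes)
  expect_equal(GenomicRanges::end(near_end), 1000)
  expect_equal(near_end$weight, 0.2)
  near_start <- extend_fragments(make_tags(50, "-"), 300, sizes)
  expect_equal(GenomicRanges::start(near_start), 1)
  expect_warning(
    out <- extend_fragments(make_tags(c(101, 2000), "+"), 300, sizes),
    "outside chromosome bounds")
  expect_length(out, 1)
})

test_that("coverage sums weights of overlapping intervals", {
  sizes <- tiny_sizes(100)
  # 0-based [0,10) and [5,15): value 2 at bases 5-9, 1 elsewhere in [0,15)
  ivls <- gr_ivl(c(1, 6), c(10, 15))
  trk <- build_coverage(ivls, sizes)
  v <- as.numeric(trk$cov$chr1)
  expect_equal(v[1:5], rep(1, 5))
  expect_equal(v[6:10], rep(2, 5))
  expect_equal(v[11:15], rep(1, 5))
  expect_equal(v[16:100], rep(0, 85))
  # fractional multi-mapper weight carried per base
  mm <- gr_ivl(21, 25)
  mm$weight <- 0.2
  expect_equal(as.numeric(build_coverage(mm, sizes)$cov$chr1)[21:25],
               rep(0.2, 5))
  # empty input gives an all-zero track
  empty <- build_coverage(gr_ivl(integer(0), integer(0)), sizes)
  expect_equal(track_total(empty), 0)
})

test_that("track total equals summed width x weight to 1e-9 relative", {
  set.seed(42)
  sizes <- tiny_sizes(5000)
  n <- 200
  start <- sample(4500, n)
  w <- sample(100, n, replace = TRUE)
  wt <- runif(n)
  gr <- gr_ivl(start, pmin(start + w, 5000))
  gr$weight <- wt
  trk <- build_coverage(gr, sizes)
  expect_equal(track_total(trk),
               sum(GenomicRanges::width(gr) * wt), tolerance = 1e-9)
})

test_that("depth normalization hits the nominal depth and is idempotent", {
  sizes <- tiny_sizes(100)
  gr <- gr_ivl(1, 50)
  gr$weight <- 1e5
  trk <- build_coverage(gr, sizes)  # total 5e6
  norm <- normalize_depth(trk)
  expect_equal(track_total(norm), 2e7)
  expect_equal(track_total(norm) / track_total(trk), 4.0)
  again <- normalize_depth(norm)
  expect_equal(as.numeric(again$cov$chr1), as.numeric(norm$cov$chr1))
  # ratio arithmetic: total 4e7 scales by 0.5
  gr$weight <- 8e5
  expect_equal(as.numeric(normalize_depth(build_coverage(gr, sizes))$cov$chr1[1]) /
                 as.numeric(build_coverage(gr, sizes)$cov$chr1[1]), 0.5)
  zero <- build_coverage(gr_ivl(integer(0), integer(0)), sizes)
  expect_error(normalize_depth(zero), "zero total weight")
})

test_that("duplicate filter caps positions at the Poisson upper quantile", {
  sizes <- tiny_sizes(10000)
  # no duplicates: unchanged
  sparse <- make_tags(seq(10, 9000, by = 10))
  expect_length(filter_excess_duplicates(sparse, 1000, 1e-3), length(sparse))

  # brute-force oracle: largest k with upper-tail P(X >= k) >= alpha
  pois_cap <- function(lambda, alpha) {
    k <- 0
    while (sum(dpois(seq(k + 1, k + 1 + 1000), lambda)) +
           ppois(k + 1001, lambda, lower.tail = FALSE) >= alpha) k <- k + 1
    k
  }
  # spike of 1000 reads where local density ~1 read/position
  lam <- 1
  spike <- suppressMessages(filter_excess_duplicates(
    make_tags(c(rep(5000, 1000), setdiff(4501:5500, 5000))), 1000, 1e-3))
  kept <- sum(GenomicRanges::start(spike) == 5000)
  lam_spike <- (1000 + 999) / 1000   # spike reads count toward the density
  expect_equal(kept, pois_cap(lam_spike, 1e-3))
  expect_lt(kept, 1000)

  # all reads at one position on an otherwise empty chromosome
  solo <- suppressMessages(filter_excess_duplicates(
    make_tags(rep(2000, 50)), 1000, 1e-3))
  expect_equal(length(solo), pois_cap(50 / 1000, 1e-3))

  expect_error(filter_excess_duplicates(sparse, 0), "local_window")
})

test_that("duplicate filter barely touches Poisson null tags", {
  set.seed(7)
  sizes <- tiny_sizes(50000)
  counts <- rpois(50000, 0.5)
  pos <- rep(seq_len(50000), counts)
  tags <- make_tags(pos)
  kept <- suppressMessages(filter_excess_duplicates(tags, 1000, 1e-3))
  removed_frac <- 1 - length(kept) / length(tags)
  expect_lt(removed_frac, 2 * 1e-3)
})

test_that("summit feature assignment follows the class priority", {
  ann <- list(promoter = gr_ivl(9001, 11000),   # TSS 10000 +/- 1 kb
              enhancer = gr_ivl(c(10500, 20001), c(12500, 21000)),
              intron = gr_ivl(30001, 40000))
  # summit 500 bp from the TSS: promoter wins over overlapping enhancer
  peaks <- gr_ivl(10400, 10600)
  res <- assign_genomic_features(peaks, ann)
  expect_equal(as.character(res$class), "promoter")
  # chromosome with no annotations is intergenic
  far <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(5000, 5200))
  expect_equal(as.character(assign_genomic_features(far, ann)$class),
               "intergenic")
  # one peak per class -> 0.25 each, fractions sum to 1, order-invariant
  four <- c(gr_ivl(9500, 9700), gr_ivl(20100, 20300),
            gr_ivl(35000, 35200), gr_ivl(60000, 60200))
  f <- assign_genomic_features(four, ann)$fractions
  expect_equal(sum(f), 1)
  expect_equal(unname(f[c("promoter", "enhancer", "intron", "intergenic")]),
               rep(0.25, 4))
  f2 <- assign_genomic_features(rev(four), ann)$fractions
  expect_equal(f, f2)
})

test_that("explicit summits override the midpoint default", {
  ann <- list(promoter = gr_ivl(1000, 2000))
  pk <- gr_ivl(1900, 4000)            # midpoint 2950: intergenic
  expect_equal(as.character(assign_genomic_features(pk, ann)$class),
               "intergenic")
  pk$summit <- 1950                   # summit inside the promoter
  expect_equal(as.character(assign_genomic_features(pk, ann)$class),
               "promoter")
})

test_that("tracks and tags round-trip through bedGraph and BED", {
  sizes <- tiny_sizes(2000)
  set.seed(3)
  gr <- gr_ivl(sample(1500, 30), sample(1501:2000, 30))
  gr$weight <- round(runif(30), 3)
  trk <- build_coverage(gr, sizes)
  bg <- file.path(tempdir(), "trk.bedGraph")
  write_bedgraph(trk, bg)
  back <- read_bedgraph(bg, sizes)
  expect_equal(as.numeric(back$cov$chr1), as.numeric(trk$cov$chr1),
               tolerance = 1e-6)
  tags <- make_tags(c(5, 100, 1999), c("+", "-", "+"), weight = c(1, 0.5, 0.2))
  bed <- file.path(tempdir(), "tags.bed")
  write_tags(tags, bed)
  rt <- read_tags(bed, sizes)
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(tags))
  expect_equal(as.character(GenomicRanges::strand(rt)),
               as.character(GenomicRanges::strand(tags)))
  expect_equal(rt$weight, tags$weight)
  cs <- file.path(tempdir(), "g.sizes")
  write_chrom_sizes(sizes, cs)
  expect_equal(read_chrom_sizes(cs), sizes)
})
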