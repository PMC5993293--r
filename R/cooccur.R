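# -- fast interval internals ------------------------------------------------
# Merged reference per chromosome as 0-based half-open start/end vectors;
# query overlap testing via findInterval on the sorted merged starts.

.merged_by_chrom <- function(gr, slop, sizes) {
  stopifnot(slop >= 0)
  exp <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(
                                  pmax(GenomicRanges::start(gr) - slop, 1L),
                                  pmin(GenomicRanges::end(gr) + slop,
                                       sizes[as.character(
                                         GenomicRanges::seqnames(gr))])))
  red <- GenomicRanges::reduce(exp)
  lapply(split(red, as.character(GenomicRanges::seqnames(red))), function(r)
    list(start0 = GenomicRanges::start(r) - 1,
         end0 = GenomicRanges::end(r)))
}

# number of query intervals (0-based starts0/ends0) overlapping the merged
# reference on one chromosome by >= 1 bp
.count_hits <- function(starts0, ends0, ref) {
  if (is.null(ref) || !length(ref$start0)) return(0L)
  j <- findInterval(ends0 - 1L, ref$start0)   # last ref starting before qe
  hit <- j >= 1 & ref$end0[pmax(j, 1)] > starts0
  sum(hit)
}

#' Count query peaks overlapping a (slop-expanded) reference set
#'
#' A query peak counts (at most once) if it intersects by at least 1 bp
#' any reference interval after expanding every reference by `slop` bp on
#' both sides; expanded references are merged first so nested references
#' are not double counted.
#'
#' @param query,reference `GRanges`.
#' @param slop symmetric reference expansion in bp (>= 0).
#' @param genome genome representation accepted by [chrom_sizes()].
#' @return integer overlap count `k`.
#' @export
count_overlaps_slop <- function(query, reference, slop = 0L, genome) {
  if (slop < 0) stop("slop must be non-negative")
  sizes <- chrom_sizes(genome)
  ref <- .merged_by_chrom(reference, slop, sizes)
  chrom <- as.character(GenomicRanges::seqnames(query))
  k <- 0L
  for (ch in unique(chrom)) {
    i <- chrom == ch
    k <- k + .count_hits(GenomicRanges::start(query)[i] - 1L,
                         GenomicRanges::end(query)[i], ref[[ch]])
  }
  k
}

#' Binomial model for chance overlap
#'
#' Under independent placement, each query peak overlaps the reference with
#' probability `p_chance` equal to the fraction of the genome covered by
#' the slop-expanded, merged reference; the chance distribution of the
#' overlap count is Binomial(n, p_chance) and significance is the upper
#' tail P(X >= k).
#'
#' @param k observed overlap count.
#' @param n number of query peaks.
#' @param reference `GRanges`.
#' @param slop reference expansion in bp.
#' @param genome genome representation accepted by [chrom_sizes()].
#' @return list of class `overlap_result`: `k`, `n`, `p_chance`,
#'   `binomial_p`, `null_mean`, `null_sd`.
#' @export
binomial_overlap_test <- function(k, n, reference, slop = 0L, genome) {
  sizes <- chrom_sizes(genome)
  ref <- .merged_by_chrom(reference, slop, sizes)
  covered <- sum(vapply(ref, function(r) sum(r$end0 - r$start0), numeric(1)))
  p <- covered / sum(as.numeric(sizes))
  if (p >= 1) {
    bp <- 1
  } else if (p <= 0) {
    bp <- if (k == 0) 1 else stop("k > 0 with zero-coverage reference")
  } else {
    bp <- pbinom(k - 1, n, p, lower.tail = FALSE)
  }
  structure(list(k = k, n = n, p_chance = p, binomial_p = bp,
                 null_mean = n * p, null_sd = sqrt(n * p * (1 - p))),
            class = "overlap_result")
}

# circular re-layout of one chromosome's peaks preserving the width and
# inter-peak gap multisets; returns sorted 0-based starts (or NULL to retry)
.rotate_once <- function(starts0, widths, L) {
  n <- length(starts0)
  ends0 <- starts0 + widths
  gaps <- if (n == 1) L - widths else
    c(starts0[-1] - ends0[-n], L - ends0[n] + starts0[1])
  j <- sample.int(n, 1)                 # which peak is laid first
  ordr <- ((j - 1 + seq_len(n) - 1) %% n) + 1
  a <- floor(runif(1, 0, L))            # start of the first laid peak
  offs <- cumsum(c(0, (widths[ordr] + gaps[ordr])[-n]))
  new_start <- (a + offs) %% L
  w_new <- widths[ordr]
  if (any(new_start + w_new > L)) return(NULL)
  o <- order(new_start)
  list(start0 = new_start[o], width = w_new[o])
}

.rotate_chrom <- function(starts0, widths, L, max_tries = 10000L) {
  if (any(widths > L)) stop("peak wider than chromosome")
  if (sum(widths) >= L) stop("peaks cover the whole chromosome")
  ord <- order(starts0)
  starts0 <- starts0[ord]
  w <- widths[ord]
  for (t in seq_len(max_tries)) {
    res <- .rotate_once(starts0, w, L)
    if (!is.null(res)) return(res)
  }
  stop("could not place rotated peaks without wrapping (coverage too dense)")
}

#' Randomize peaks retaining inter-peak distances
#'
#' Per chromosome, the circular sequence of (peak width, following gap)
#' pairs is rotated to a random first peak and re-laid from a uniformly
#' random start position; draws that would wrap a peak around the
#' chromosome end are rejected and redrawn. The per-chromosome multisets of
#' peak widths and inter-peak gaps are preserved exactly.
#'
#' @param peaks `GRanges`.
#' @param genome genome representation accepted by [chrom_sizes()].
#' @param seed optional RNG seed for reproducibility.
#' @return randomized `GRanges` (sorted within chromosome).
#' @export
randomize_retaining_gaps <- function(peaks, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- chrom_sizes(genome)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  si <- .seqinfo(sizes)
  pieces <- lapply(unique(chrom), function(ch) {
    i <- chrom == ch
    r <- .rotate_chrom(GenomicRanges::start(peaks)[i] - 1L,
                       GenomicRanges::width(peaks)[i], sizes[[ch]])
    GenomicRanges::GRanges(ch, IRanges::IRanges(r$start0 + 1L,
                                                width = r$width),
                           seqinfo = si)
  })
  do.call(c, pieces)
}

#' Empirical overlap test with gap-retaining randomization
#'
#' Repeats the overlap count against `n_rand` (default 900) gap-retaining
#' randomizations of the query peaks (optionally of both sets) and reports
#' the add-one empirical P value `(1 + #{k_rand >= k_obs}) / (n_rand + 1)`,
#' so zero is unattainable.
#'
#' @param query,reference `GRanges`.
#' @param slop reference expansion in bp.
#' @param genome genome representation accepted by [chrom_sizes()].
#' @param n_rand number of randomizations.
#' @param seed RNG seed.
#' @param randomize `"query"` (default) or `"both"`.
#' @return `overlap_result` list with `empirical_p`, `null_mean`,
#'   `null_sd`, `null_counts`, `n_rand`, plus the binomial-model fields.
#' @export
empirical_overlap_test <- function(query, reference, slop = 0L, genome,
                                   n_rand = 900L, seed = 1L,
                                   randomize = c("query", "both")) {
  randomize <- match.arg(randomize)
  stopifnot(n_rand >= 1)
  sizes <- chrom_sizes(genome)
  k_obs <- count_overlaps_slop(query, reference, slop, genome)
  binom <- binomial_overlap_test(k_obs, length(query), reference, slop, genome)
  qch <- as.character(GenomicRanges::seqnames(query))
  q_by <- lapply(split(seq_along(query), qch), function(i)
    list(width = GenomicRanges::width(query)[i][order(GenomicRanges::start(query)[i])],
         start0 = sort(GenomicRanges::start(query)[i] - 1L)))
  rch <- as.character(GenomicRanges::seqnames(reference))
  r_by <- lapply(split(seq_along(reference), rch), function(i)
    list(width = GenomicRanges::width(reference)[i][order(GenomicRanges::start(reference)[i])],
         start0 = sort(GenomicRanges::start(reference)[i] - 1L)))
  merged_ref <- .merged_by_chrom(reference, slop, sizes)
  set.seed(seed)
  null_counts <- integer(n_rand)
  for (b in seq_len(n_rand)) {
    ref_b <- merged_ref
    if (randomize == "both") {
      ref_b <- lapply(names(r_by), function(ch) {
        r <- .rotate_chrom(r_by[[ch]]$start0, r_by[[ch]]$width, sizes[[ch]])
        s0 <- pmax(r$start0 - slop, 0)
        e0 <- pmin(r$start0 + r$width + slop, sizes[[ch]])
        # merge
        keep_s <- numeric(0); keep_e <- numeric(0)
        for (i in seq_along(s0)) {
          if (length(keep_e) && s0[i] <= keep_e[length(keep_e)]) {
            keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e0[i])
          } else {
            keep_s <- c(keep_s, s0[i]); keep_e <- c(keep_e, e0[i])
          }
        }
        list(start0 = keep_s, end0 = keep_e)
      })
      names(ref_b) <- names(r_by)
    }
    k <- 0L
    for (ch in names(q_by)) {
      r <- .rotate_chrom(q_by[[ch]]$start0, q_by[[ch]]$width, sizes[[ch]])
      k <- k + .count_hits(r$start0, r$start0 + r$width, ref_b[[ch]])
    }
    null_counts[b] <- k
  }
  binom$empirical_p <- (1 + sum(null_counts >= k_obs)) / (n_rand + 1)
  binom$null_mean_emp <- mean(null_counts)
  binom$null_sd_emp <- sd(null_counts)
  binom$null_counts <- null_counts
  binom$n_rand <- n_rand
  binom$randomize <- randomize
  binom
}

#' Binary co-association of two datasets over a common region set
#'
#' From the 2x2 table of joint presence/absence over regions (a = both,
#' b = first only, c = second only, d = neither) computes the phi-squared
#' statistic (identical to Pearson's r^2 applied to the binary indicator
#' vectors) and the Jaccard index a / (a + b + c).
#'
#' @param indicator_a,indicator_b logical (or 0/1) vectors of equal length.
#' @return list of class `coassociation`: `phi2`, `jaccard`, `table`.
#' @export
coassociation <- function(indicator_a, indicator_b) {
  stopifnot(length(indicator_a) == length(indicator_b))
  A <- as.logical(indicator_a)
  B <- as.logical(indicator_b)
  a <- sum(A & B); b <- sum(A & !B); c_ <- sum(!A & B); d <- sum(!A & !B)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) {
    warning("constant indicator vector: phi2 undefined")
    phi2 <- NaN
  } else {
    phi2 <- (a * d - b * c_)^2 / denom
  }
  jac <- if (a + b + c_ == 0) NaN else a / (a + b + c_)
  structure(list(phi2 = phi2, jaccard = jac,
                 table = c(a = a, b = b, c = c_, d = d)),
            class = "coassociation")
}

#' Rank datasets by co-association with a reference indicator
#'
#' @param indicators named list of logical vectors (one per dataset).
#' @param reference logical vector over the same regions.
#' @return data.frame (`dataset`, `phi2`, `jaccard`, `rank`) ordered by
#'   descending phi2, ties broken by descending Jaccard then dataset name.
#' @export
coassociation_rank <- function(indicators, reference) {
  stopifnot(!is.null(names(indicators)))
  rows <- lapply(names(indicators), function(nm) {
    co <- suppressWarnings(coassociation(indicators[[nm]], reference))
    data.frame(dataset = nm, phi2 = co$phi2, jaccard = co$jaccard,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$phi2, -out$jaccard, out$dataset), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
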