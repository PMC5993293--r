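#' Cut-site / coverage track
#'
#' A `cut_track` stores per-base summed read weights per chromosome as a
#' numeric `RleList`, together with the fragment length used to build it
#' (1 bp for individual DNase cut sites, 200 bp for DHS recovered DNA,
#' 300 bp for ChIP).
#'
#' @param cov named `RleList` (or list of numeric vectors) of per-base
#'   weights, one element per chromosome.
#' @param fragment_length integer, extension used when building the track.
#' @return object of class `cut_track` with elements `cov`,
#'   `fragment_length` and `total_weight`.
#' @export
cut_track <- function(cov, fragment_length = 1L) {
  if (!is(cov, "RleList")) {
    cov <- IRanges::RleList(lapply(cov, function(v)
      S4Vectors::Rle(as.numeric(v))), compress = FALSE)
  }
  stopifnot(!is.null(names(cov)), fragment_length >= 1)
  total <- sum(vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)),
                      numeric(1)))
  if (any(unlist(lapply(cov, function(r) any(S4Vectors::runValue(r) < 0)))))
    stop("track values must be non-negative")
  structure(list(cov = cov,
                 fragment_length = as.integer(fragment_length),
                 total_weight = total),
            class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  cat(sprintf("cut_track: %d chromosome(s), fragment length %d bp, total weight %.6g\n",
              length(x$cov), x$fragment_length, x$total_weight))
  invisible(x)
}

#' Total read weight of a track
#' @param track a `cut_track`.
#' @return numeric scalar.
#' @export
track_total <- function(track) track$total_weight

#' Build per-base coverage from weighted intervals
#'
#' Per-base value is the sum of the weights of all overlapping intervals,
#' so fractional multi-mapper contributions are carried through and the
#' mean over any window equals the mean number of overlapping fragments
#' per base pair.
#'
#' @param intervals `GRanges` with a numeric `weight` metadata column
#'   (missing weights default to 1).
#' @param genome genome representation accepted by [chrom_sizes()].
#' @param fragment_length recorded on the returned track (metadata only).
#' @return a [cut_track()].
#' @export
build_coverage <- function(intervals, genome, fragment_length = 1L) {
  sizes <- chrom_sizes(genome)
  w <- intervals$weight
  if (is.null(w)) w <- rep(1, length(intervals))
  stopifnot(all(w >= 0))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(intervals),
                               IRanges::ranges(intervals),
                               seqinfo = .seqinfo(sizes))
  cov <- GenomicRanges::coverage(gr, weight = w)
  cov <- cov[names(sizes)]
  cut_track(cov, fragment_length = fragment_length)
}

#' Scale a track to a nominal sequencing depth
#'
#' Rescales all per-base values by `nominal_depth / total_weight` so the
#' track's total read weight equals the nominal depth (default 20 million
#' reads). Idempotent on a track already at nominal depth.
#'
#' @param track a [cut_track()].
#' @param nominal_depth target total read weight.
#' @return rescaled `cut_track`.
#' @export
normalize_depth <- function(track, nominal_depth = 2e7) {
  stopifnot(is(track, "cut_track"), nominal_depth > 0)
  if (track$total_weight <= 0)
    stop("cannot depth-normalize a track with zero total weight")
  scale_track(track, nominal_depth / track$total_weight)
}

#' Multiply all track values by a scalar
#' @param track a [cut_track()].
#' @param factor positive scale factor.
#' @return scaled `cut_track`.
#' @export
scale_track <- function(track, factor) {
  stopifnot(is(track, "cut_track"), factor >= 0)
  cut_track(track$cov * factor, fragment_length = track$fragment_length)
}

#' Sum of track weight inside a set of intervals
#' @param track a [cut_track()].
#' @param regions `GRanges`.
#' @return numeric scalar total weight under `regions` (overlap-merged).
#' @export
track_weight_in <- function(track, regions) {
  red <- GenomicRanges::reduce(regions)
  by_chrom <- split(IRanges::ranges(red),
                    as.character(GenomicRanges::seqnames(red)))
  tot <- 0
  for (chrom in names(by_chrom)) {
    if (!chrom %in% names(track$cov)) next
    r <- by_chrom[[chrom]]
    r <- IRanges::restrict(r, start = 1L, end = length(track$cov[[chrom]]))
    r <- r[IRanges::width(r) > 0]
    if (!length(r)) next
    tot <- tot + sum(IRanges::viewSums(IRanges::Views(track$cov[[chrom]], r)))
  }
  tot
}

#' Write / read bedGraph tracks
#'
#' Values are written with six decimal places; zero-valued runs are
#' omitted, the standard sparse bedGraph convention.
#'
#' @param track a [cut_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$cov), function(chrom) {
    r <- track$cov[[chrom]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl) + 1
    keep <- rv != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start0 = starts[keep] - 1,
               end0 = ends[keep], value = rv[keep])
  })
  tab <- do.call(rbind, grl)
  if (is.null(tab)) tab <- data.frame(chrom = character(), start0 = numeric(),
                                      end0 = numeric(), value = numeric())
  tab$start0 <- sprintf("%.0f", tab$start0)
  tab$end0 <- sprintf("%.0f", tab$end0)
  tab$value <- sprintf("%.6f", tab$value)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param sizes named chromosome lengths (defines the coordinate space and
#'   zero-fills uncovered bases).
#' @param fragment_length recorded on the returned track.
#' @return for the reader, a [cut_track()].
#' @export
read_bedgraph <- function(path, sizes, fragment_length = 1L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- as.integer(sizes)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  cut_track(cov[names(sizes)], fragment_length = fragment_length)
}
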