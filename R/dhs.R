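#' Anchor cross-sample DHS normalization on peak cut-site totals
#'
#' Scales each sample's cut-site track so that the total read-start weight
#' mapping under predicted DHS peaks is equal across samples; differences in
#' the fraction of reads at background, non-hypersensitive regions then do
#' not affect the accessibility measurement. The common target is the
#' geometric mean of the samples' in-peak totals, which makes the result
#' invariant to sample order. Valid under the assumption that mean
#' accessibility over all DHS regions genome-wide is approximately equal
#' across samples.
#'
#' @param tracks named list of [cut_track()]s at cut-site (1 bp) resolution.
#' @param dhs_peaks `GRanges` of DHS peaks.
#' @return list with `tracks` (scaled), `scale_factors` and
#'   `in_peak_totals` (pre-scaling).
#' @export
dhs_anchor_normalize <- function(tracks, dhs_peaks) {
  stopifnot(length(tracks) >= 2, length(dhs_peaks) >= 1)
  if (is.null(names(tracks)))
    names(tracks) <- paste0("sample", seq_along(tracks))
  totals <- vapply(tracks, track_weight_in, numeric(1), regions = dhs_peaks)
  if (any(totals <= 0))
    stop("sample(s) with zero in-peak weight: ",
         paste(names(tracks)[totals <= 0], collapse = ", "))
  target <- exp(mean(log(totals)))
  scales <- target / totals
  out <- mapply(scale_track, tracks, scales, SIMPLIFY = FALSE)
  list(tracks = out, scale_factors = scales, in_peak_totals = totals)
}

#' Mean cut frequency in anchored windows
#'
#' Computes the mean per-base cut weight of a track in windows anchored on
#' each region's midpoint (the TSS, when regions are symmetric promoter
#' intervals or width-1 TSS points). Supported windows: `"tss600"`
#' (+/- 600 bp around the anchor, 1200 bp), `"upstream1kb"` (the 1 kb
#' interval 5' of the anchor on the region's strand) and `"mid600"`
#' (+/- 600 bp around the midpoint, for enhancers). Windows clipped at
#' chromosome edges are renormalised by their realised width.
#'
#' @param track a [cut_track()].
#' @param regions stranded `GRanges`; the anchor is the interval midpoint.
#' @param window one of `"tss600"`, `"upstream1kb"`, `"mid600"`.
#' @return data.frame with `region` (names or index), `mean_cut_frequency`.
#' @export
window_mean_cut_frequency <- function(track, regions,
                                      window = c("tss600", "upstream1kb",
                                                 "mid600")) {
  window <- match.arg(window)
  anchors <- .summits(regions)
  a <- GenomicRanges::start(anchors)  # 1-based anchor position
  str <- as.character(GenomicRanges::strand(regions))
  if (window == "upstream1kb") {
    if (any(str == "*"))
      stop("upstream1kb window requires stranded regions")
    ws <- ifelse(str == "+", a - 1000L, a + 1L)
    we <- ifelse(str == "+", a - 1L, a + 1000L)
  } else {
    ws <- a - 600L
    we <- a + 599L
  }
  chrom <- as.character(GenomicRanges::seqnames(regions))
  len <- setNames(
    vapply(track$cov, length, integer(1))[chrom], NULL)
  cs <- pmax(ws, 1L)
  ce <- pmin(we, len)
  if (any(ce < cs)) stop("window entirely outside chromosome bounds")
  means <- numeric(length(regions))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- IRanges::Views(track$cov[[ch]], IRanges::IRanges(cs[i], ce[i]))
    means[i] <- IRanges::viewSums(v) / (ce[i] - cs[i] + 1)
  }
  ids <- if (!is.null(names(regions)) && any(nzchar(names(regions))))
    names(regions) else as.character(seq_along(regions))
  data.frame(region = ids, mean_cut_frequency = means,
             stringsAsFactors = FALSE)
}

#' Accessibility deltas between two conditions
#'
#' @param track_a,track_b [cut_track()]s for the two conditions (already
#'   DHS-anchor normalised).
#' @param regions stranded `GRanges`.
#' @inheritParams window_mean_cut_frequency
#' @return data.frame with `region`, `mean_a`, `mean_b`, `delta`
#'   (`mean_a - mean_b`).
#' @export
accessibility_delta <- function(track_a, track_b, regions,
                                window = "upstream1kb") {
  sa <- window_mean_cut_frequency(track_a, regions, window)
  sb <- window_mean_cut_frequency(track_b, regions, window)
  data.frame(region = sa$region, mean_a = sa$mean_cut_frequency,
             mean_b = sb$mean_cut_frequency,
             delta = sa$mean_cut_frequency - sb$mean_cut_frequency,
             stringsAsFactors = FALSE)
}

#' Empirical-null accessibility thresholds
#'
#' Order-statistic thresholds for calling regulated accessibility: a region
#' is a candidate only if its accessibility change exceeds the changes
#' exhibited by `percentile`% of the reference (factor-negative) regions.
#' Thresholds use linear interpolation between order statistics (type-7
#' quantiles) of the signed null deltas: the upper threshold at the
#' `percentile`-th percentile, the lower at the `(100 - percentile)`-th.
#'
#' @param null_deltas numeric deltas at factor-negative regions (>= 100).
#' @param percentile per-tail percentile, typically 95 (loose) or 99
#'   (strict).
#' @return list of class `null_thresholds` with `theta_up`, `theta_down`,
#'   `percentile`, `n_null`.
#' @export
fit_null_thresholds <- function(null_deltas, percentile = 95) {
  null_deltas <- null_deltas[is.finite(null_deltas)]
  if (length(null_deltas) < 100)
    stop("need >= 100 null deltas to fit empirical thresholds")
  stopifnot(percentile >= 50, percentile < 100)
  up <- unname(quantile(null_deltas, percentile / 100, type = 7))
  down <- unname(quantile(null_deltas, 1 - percentile / 100, type = 7))
  structure(list(theta_up = up, theta_down = down,
                 percentile = percentile, n_null = length(null_deltas)),
            class = "null_thresholds")
}

#' Call differential accessibility against empirical nulls
#'
#' A region is called `increased` iff its delta strictly exceeds the upper
#' threshold, `decreased` iff strictly below the lower threshold, else
#' `unchanged`; calls are made at both the loose (default 95th percentile)
#' and strict (default 99th) cutoffs, so strict calls are always a subset
#' of loose calls.
#'
#' @param deltas data.frame from [accessibility_delta()] (or any frame with
#'   `region` and `delta`).
#' @param thresholds_loose,thresholds_strict `null_thresholds` objects
#'   fitted on the same delta definition.
#' @return data.frame with `region`, `delta`, `call_loose`, `call_strict`
#'   plus a `fractions` attribute (per call per cutoff).
#' @export
call_differential_accessibility <- function(deltas, thresholds_loose,
                                            thresholds_strict = NULL) {
  stopifnot(is(thresholds_loose, "null_thresholds"))
  call_one <- function(d, th) {
    ifelse(d > th$theta_up, "increased",
           ifelse(d < th$theta_down, "decreased", "unchanged"))
  }
  out <- data.frame(region = deltas$region, delta = deltas$delta,
                    call_loose = call_one(deltas$delta, thresholds_loose),
                    stringsAsFactors = FALSE)
  if (!is.null(thresholds_strict)) {
    stopifnot(is(thresholds_strict, "null_thresholds"),
              thresholds_strict$percentile >= thresholds_loose$percentile)
    out$call_strict <- call_one(deltas$delta, thresholds_strict)
  }
  frac <- function(x) setNames(
    as.numeric(table(factor(x, c("increased", "decreased", "unchanged")))) /
      length(x), c("increased", "decreased", "unchanged"))
  attr(out, "fractions") <- list(
    loose = frac(out$call_loose),
    strict = if (!is.null(out$call_strict)) frac(out$call_strict))
  out
}
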