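# -- hexamer machinery ------------------------------------------------------
# The 6-bp context of a cut at base x is registered symmetrically: bases
# x-3 .. x+2 on the forward strand (3 bases 5' and 3 bases 3' of the cut).
# The registration is isolated here so it can be changed in one place.

.BASE_CODE <- setNames(c(0L, 1L, 2L, 3L), c("A", "C", "G", "T"))

# integer base codes (0..3, NA for anything else) for one chromosome
.base_codes <- function(seq) {
  chars <- utf8ToInt(as.character(seq))
  code <- rep(NA_integer_, length(chars))
  code[chars == utf8ToInt("A")] <- 0L
  code[chars == utf8ToInt("C")] <- 1L
  code[chars == utf8ToInt("G")] <- 2L
  code[chars == utf8ToInt("T")] <- 3L
  code
}

# hexamer code (0..4095, NA where undefined) covering the cut at each base:
# code[x] encodes bases x-3 .. x+2
.hexamer_codes <- function(base_codes) {
  n <- length(base_codes)
  out <- rep(NA_real_, n)
  if (n < 6) return(out)
  start_code <- numeric(n - 5)  # hexamer starting at position i
  start_code[] <- 0
  ok <- rep(TRUE, n - 5)
  for (k in 0:5) {
    b <- base_codes[(1 + k):(n - 5 + k)]
    ok <- ok & !is.na(b)
    start_code <- start_code + ifelse(is.na(b), 0, b) * 4^(5 - k)
  }
  start_code[!ok] <- NA_real_
  # hexamer covering cut at x starts at x - 3
  out[4:(n - 2)] <- start_code
  out
}

#' Learn the DNase-I hexamer cleavage-bias model
#'
#' DNase-I cleaves with a strong intrinsic preference that depends on the
#' surrounding 6-bp sequence. The expected relative cut rate of each of the
#' 4^6 contexts is learned as the mean cut frequency at all positions with
#' that context inside DNase-hypersensitive (DHS) regions, with a
#' pseudocount of `pseudocount` observations at the DHS-wide mean rate per
#' context so all rates stay strictly positive. Contexts containing N are
#' excluded.
#'
#' @param track a [cut_track()] at cut-site resolution.
#' @param dhs_regions `GRanges` of DHS regions (bias is learned only
#'   inside them).
#' @param genome named `DNAStringSet`.
#' @param pseudocount pseudo-observations per context (default 1).
#' @return object of class `hexamer_bias`: `rate` (length 4096),
#'   `mean_rate`, `context_counts`, `pseudocount`.
#' @export
learn_hexamer_bias <- function(track, dhs_regions, genome, pseudocount = 1) {
  stopifnot(is(track, "cut_track"), is(genome, "DNAStringSet"))
  if (!length(dhs_regions)) stop("DHS regions are empty")
  if (sum(Biostrings::width(genome)) == 0) stop("genome sequence is empty")
  red <- GenomicRanges::reduce(dhs_regions)
  wsum <- numeric(4096)
  counts <- numeric(4096)
  for (chrom in unique(as.character(GenomicRanges::seqnames(red)))) {
    if (!chrom %in% names(genome) || !chrom %in% names(track$cov)) next
    codes <- .hexamer_codes(.base_codes(genome[[chrom]]))
    cov <- as.numeric(track$cov[[chrom]])
    r <- red[as.character(GenomicRanges::seqnames(red)) == chrom]
    pos <- unlist(lapply(seq_along(r), function(i)
      seq(GenomicRanges::start(r)[i], GenomicRanges::end(r)[i])))
    pos <- pos[pos >= 1 & pos <= length(codes)]
    h <- codes[pos]
    keep <- !is.na(h)
    h <- h[keep]
    pos <- pos[keep]
    if (!length(pos)) next
    f <- factor(h, levels = 0:4095)
    counts <- counts + tabulate(f, nbins = 4096)
    s <- rowsum(cov[pos], f)
    wsum[as.integer(rownames(s)) + 1] <- wsum[as.integer(rownames(s)) + 1] + s[, 1]
  }
  if (sum(counts) == 0) stop("no usable DHS positions for bias learning")
  mean_rate <- sum(wsum) / sum(counts)
  if (any(counts == 0))
    message(sum(counts == 0),
            " context(s) unobserved in DHS regions; pseudocount falls back to the global mean")
  rate <- (wsum + pseudocount * mean_rate) / (counts + pseudocount)
  structure(list(rate = rate, mean_rate = mean_rate,
                 context_counts = counts, pseudocount = pseudocount),
            class = "hexamer_bias")
}

# expected per-base rates for a window of genome positions on one chromosome
.expected_rates <- function(bias, codes, positions) {
  h <- codes[positions]
  out <- rep(bias$mean_rate, length(positions))
  ok <- !is.na(h)
  out[ok] <- bias$rate[h[ok] + 1]
  out
}

#' Bias-corrected aggregate footprint profile
#'
#' Aggregates observed cut frequencies across aligned, strand-oriented
#' motif instances and divides, per aligned position, the mean observed cut
#' weight by the mean expected rate implied by each instance's local 6-bp
#' context; minus-strand instances are coordinate-reversed before
#' aggregation. After bias correction a ratio of 1 means cutting at the
#' sequence-expected rate; bound factors can raise as well as lower the
#' ratio within the motif.
#'
#' @param track a [cut_track()] at cut-site resolution.
#' @param motif_instances stranded `GRanges` of equal-width motif matches.
#' @param bias a `hexamer_bias` model learned on the same track/DHS set.
#' @param genome named `DNAStringSet`.
#' @param flank bp of context either side of the motif (default 50).
#' @return object of class `footprint_profile`: `position` (relative to
#'   motif start), `ratio`, `n_instances`, `motif_width`, `flank`, and the
#'   per-instance `obs` / `expected` matrices used for resampling.
#' @export
footprint_profile <- function(track, motif_instances, bias, genome,
                              flank = 50L) {
  stopifnot(is(bias, "hexamer_bias"), length(motif_instances) > 0)
  w <- unique(GenomicRanges::width(motif_instances))
  if (length(w) != 1) stop("motif instances must share one width")
  L <- w + 2L * flank
  chrom <- as.character(GenomicRanges::seqnames(motif_instances))
  str <- as.character(GenomicRanges::strand(motif_instances))
  obs <- matrix(NA_real_, length(motif_instances), L)
  expd <- matrix(NA_real_, length(motif_instances), L)
  for (ch in unique(chrom)) {
    codes <- .hexamer_codes(.base_codes(genome[[ch]]))
    cov <- as.numeric(track$cov[[ch]])
    idx <- which(chrom == ch)
    for (i in idx) {
      s <- GenomicRanges::start(motif_instances)[i]
      e <- GenomicRanges::end(motif_instances)[i]
      posn <- if (str[i] == "-") seq(e + flank, s - flank) else
        seq(s - flank, e + flank)
      if (min(posn) < 1 || max(posn) > length(cov)) next
      obs[i, ] <- cov[posn]
      expd[i, ] <- .expected_rates(bias, codes, posn)
    }
  }
  ok <- stats::complete.cases(obs)
  if (!any(ok)) stop("no motif instance windows fall inside the genome")
  if (any(!ok))
    warning(sum(!ok), " instance(s) dropped: window outside chromosome")
  obs <- obs[ok, , drop = FALSE]
  expd <- expd[ok, , drop = FALSE]
  me <- colMeans(expd)
  if (any(me <= 0)) stop("zero expected rate in profile (corrupt bias model)")
  structure(list(position = seq(-flank, w + flank - 1L),
                 ratio = colMeans(obs) / me,
                 n_instances = sum(ok), motif_width = w, flank = flank,
                 obs = obs, expected = expd),
            class = "footprint_profile")
}

# profile indices of the central window and background positions
.magnitude_windows <- function(profile, central_width, background) {
  w <- profile$motif_width
  flank <- profile$flank
  centre_idx <- flank + floor(w / 2) + 1L        # index of motif-centre base
  half <- central_width / 2
  central <- (centre_idx - floor(half)):(centre_idx + ceiling(half) - 1L)
  d <- abs(seq_along(profile$ratio) - centre_idx)
  bg <- which(d >= background[1] & d <= background[2])
  if (background[1] <= ceiling(half))
    stop("background overlaps the central window")
  if (!length(bg) || max(d) < background[2])
    stop("flank too narrow for the requested background")
  list(central = central, background = bg)
}

#' Footprint magnitude
#'
#' The footprint magnitude is the difference to background of the mean
#' observed/expected cut frequency across the `central_width` (default
#' 10) bp surrounding the motif centre; background is the mean ratio over
#' positions `background[1]`..`background[2]` bp from the centre on both
#' sides (default 21-50). Sign is retained: protection gives negative
#' magnitudes, induced exposure positive ones. Note the score can
#' understate asymmetric or complex footprints.
#'
#' @param profile a [footprint_profile()].
#' @param central_width central window width in bp.
#' @param background two-element numeric, distance range from motif centre.
#' @return list of class `footprint_magnitude`: `magnitude`, `se`
#'   (standard error over instances), `n_instances`.
#' @export
footprint_magnitude <- function(profile, central_width = 10,
                                background = c(21, 50)) {
  win <- .magnitude_windows(profile, central_width, background)
  m <- mean(profile$ratio[win$central]) - mean(profile$ratio[win$background])
  # per-instance magnitudes for a spread estimate
  per <- rowMeans(profile$obs[, win$central, drop = FALSE]) /
    rowMeans(profile$expected[, win$central, drop = FALSE]) -
    rowMeans(profile$obs[, win$background, drop = FALSE]) /
      rowMeans(profile$expected[, win$background, drop = FALSE])
  structure(list(magnitude = m,
                 se = stats::sd(per) / sqrt(profile$n_instances),
                 n_instances = profile$n_instances,
                 central_width = central_width, background = background),
            class = "footprint_magnitude")
}

#' Compare footprint magnitudes between conditions
#'
#' Computes the difference in footprint magnitude between a control and a
#' knockdown profile for the same motif, with a bootstrap standard error
#' from resampling motif instances within each condition.
#'
#' @param profile_control,profile_knockdown [footprint_profile()]s built
#'   with the same motif set and flank.
#' @param central_width,background as in [footprint_magnitude()].
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list: `delta_m` (control minus knockdown), `m_control`,
#'   `m_knockdown`, `se_boot`.
#' @export
compare_footprints <- function(profile_control, profile_knockdown,
                               central_width = 10, background = c(21, 50),
                               n_boot = 1000, seed = 1) {
  if (profile_control$motif_width != profile_knockdown$motif_width ||
      profile_control$flank != profile_knockdown$flank)
    stop("profiles disagree on motif width or flank")
  mc <- footprint_magnitude(profile_control, central_width, background)
  mk <- footprint_magnitude(profile_knockdown, central_width, background)
  win <- .magnitude_windows(profile_control, central_width, background)
  boot_m <- function(p) {
    i <- sample.int(p$n_instances, replace = TRUE)
    r <- colMeans(p$obs[i, , drop = FALSE]) /
      colMeans(p$expected[i, , drop = FALSE])
    mean(r[win$central]) - mean(r[win$background])
  }
  set.seed(seed)
  dm <- replicate(n_boot, boot_m(profile_control) - boot_m(profile_knockdown))
  list(delta_m = mc$magnitude - mk$magnitude,
       m_control = mc$magnitude, m_knockdown = mk$magnitude,
       se_boot = stats::sd(dm), n_boot = n_boot)
}
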