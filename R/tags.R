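#' Read / write mapped read tags as BED
#'
#' Tags are width-1 stranded positions (the 5' mapped base of each read)
#' with a fractional `weight` in (0, 1]; a read mapping to k locations
#' contributes weight 1/k at each. On disk the weight travels in the BED
#' score column.
#'
#' @param path BED file path.
#' @param sizes named chromosome lengths.
#' @return `GRanges` with `weight` metadata column.
#' @export
read_tags <- function(path, sizes) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- as.integer(sizes)
  gr$weight <- if (is.null(gr$score)) rep(1, length(gr)) else gr$score
  gr$score <- NULL
  gr
}

#' @rdname read_tags
#' @param tags `GRanges` of tags with `weight`.
#' @export
write_tags <- function(tags, path) {
  out <- tags
  out$score <- if (is.null(tags$weight)) rep(1, length(tags)) else tags$weight
  out$weight <- NULL
  out$name <- if (is.null(out$name)) rep(".", length(out)) else out$name
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Extend read tags to fragment-sized intervals
#'
#' Each tag is extended 3'-ward from its mapped start on its own strand to
#' the mean fragment size of the sample DNA (300 bp for ChIP, 200 bp for
#' DHS recovered DNA, 1 bp for individual DNase cut sites). Intervals are
#' clipped at chromosome edges rather than discarded; tags lying outside
#' chromosome bounds are rejected with a warning.
#'
#' @param tags `GRanges` of width-1 stranded tags with `weight`.
#' @param fragment_length extension length in bp (>= 1).
#' @param genome genome representation accepted by [chrom_sizes()].
#' @return `GRanges` of fragment intervals, weights preserved.
#' @export
extend_fragments <- function(tags, fragment_length, genome) {
  stopifnot(fragment_length >= 1)
  sizes <- chrom_sizes(genome)
  si <- .seqinfo(sizes)
  ok <- as.character(GenomicRanges::seqnames(tags)) %in% names(sizes) &
    GenomicRanges::start(tags) >= 1 &
    GenomicRanges::end(tags) <= sizes[as.character(GenomicRanges::seqnames(tags))]
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " tag(s) outside chromosome bounds rejected")
    tags <- tags[ok]
  }
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(tags),
                               IRanges::ranges(tags),
                               strand = GenomicRanges::strand(tags),
                               seqinfo = si)
  # resize may transiently leave the chromosome before clipping
  gr <- suppressWarnings(
    GenomicRanges::resize(gr, width = as.integer(fragment_length),
                          fix = "start"))
  gr <- GenomicRanges::trim(gr)
  gr$weight <- if (is.null(tags$weight)) rep(1, length(tags)) else tags$weight
  gr
}

#' Remove statistically excess duplicate reads
#'
#' Reads mapping to the exact same (chromosome, start, strand) position are
#' capped at the largest count that is not statistically surprising under a
#' Poisson model whose mean is the local per-position read density,
#' estimated strand-specifically in a centred window. The cap is
#' `qpois(1 - alpha, lambda)`: the largest k whose upper-tail probability
#' P(X >= k) still reaches `alpha`. Excess reads above the cap (likely PCR
#' artefacts) are discarded; at least one read per occupied position is
#' always retained.
#'
#' @param tags `GRanges` of width-1 stranded tags.
#' @param local_window window width in bp for the local density (default
#'   1000).
#' @param alpha upper-tail significance level (default 1e-3).
#' @return filtered `GRanges`; attribute `n_removed` records the number of
#'   discarded reads.
#' @export
filter_excess_duplicates <- function(tags, local_window = 1000L,
                                     alpha = 1e-3) {
  if (local_window < 1) stop("local_window must be >= 1")
  if (!length(tags)) return(tags)
  key <- paste(as.character(GenomicRanges::seqnames(tags)),
               as.character(GenomicRanges::strand(tags)))
  keep <- logical(length(tags))
  hw <- local_window / 2
  for (grp in split(seq_along(tags), key)) {
    pos <- GenomicRanges::start(tags)[grp]
    ord <- order(pos)
    sorted <- pos[ord]
    uniq <- unique(sorted)
    cnt <- tabulate(match(sorted, uniq))
    # reads (same strand) within the centred window, incl. the position itself
    nloc <- findInterval(uniq + hw, sorted) -
      findInterval(uniq - hw - 1e-9, sorted)
    lambda <- nloc / local_window
    cap <- pmax(1L, qpois(1 - alpha, lambda))
    take <- pmin(cnt, cap)
    # keep the first `take` reads at each position (sorted order)
    offs <- cumsum(c(0, head(cnt, -1)))
    sel <- unlist(mapply(function(o, k) o + seq_len(k), offs, take,
                         SIMPLIFY = FALSE))
    keep[grp[ord][sel]] <- TRUE
  }
  out <- tags[keep]
  attr(out, "n_removed") <- sum(!keep)
  if (sum(!keep) > 0)
    message(sum(!keep), " excess duplicate read(s) removed")
  out
}
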