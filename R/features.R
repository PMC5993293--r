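#' Assign peak summits to genomic feature classes
#'
#' Each peak summit (supplied, or the interval midpoint with ties to the
#' lower coordinate) is assigned exactly one class with the priority
#' promoter > TTS > enhancer > exon > intron > intergenic, and the fraction
#' of summits per class is reported. Promoters and transcript end regions
#' are conventionally the intervals within 1 kb of annotated transcript
#' starts and ends; enhancers the intervals within 1 kb of H3K4me1 peak
#' summits.
#'
#' @param peaks `GRanges`; an integer `summit` metadata column (1-based
#'   coordinate) overrides the midpoint default.
#' @param annotations named list of `GRanges` with any of the elements
#'   `promoter`, `tts`, `enhancer`, `exon`, `intron`.
#' @return list with `class` (factor per peak, input order) and `fractions`
#'   (named numeric summing to 1 over all six classes).
#' @export
assign_genomic_features <- function(peaks, annotations) {
  classes <- c("promoter", "tts", "enhancer", "exon", "intron")
  if (!length(peaks)) stop("no peaks supplied")
  if (!is.null(peaks$summit)) {
    summ <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                   IRanges::IRanges(peaks$summit, width = 1))
  } else {
    summ <- .summits(peaks)
  }
  assigned <- rep("intergenic", length(peaks))
  remaining <- rep(TRUE, length(peaks))
  for (cl in classes) {
    ann <- annotations[[cl]]
    if (is.null(ann) || !length(ann)) next
    hit <- suppressWarnings(
      IRanges::overlapsAny(summ, ann, ignore.strand = TRUE))
    take <- hit & remaining
    assigned[take] <- cl
    remaining[take] <- FALSE
  }
  lev <- c(classes, "intergenic")
  cls <- factor(assigned, levels = lev)
  list(class = cls,
       fractions = setNames(as.numeric(table(cls)) / length(peaks), lev))
}
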