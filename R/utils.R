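#' @importFrom methods is
#' @importFrom stats quantile rnorm rpois runif rbinom setNames pt pbinom
#'   qpois p.adjust cor sd rlnorm
#' @importFrom utils read.delim write.table head
NULL

#' Extract named chromosome lengths
#'
#' Accepts a named `DNAStringSet` (lengths taken from sequence widths), a
#' `Seqinfo`, or a named numeric vector, and returns a named integer vector
#' of chromosome lengths.
#'
#' @param genome genome representation.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stopifnot(!is.null(names(genome)), !anyDuplicated(names(genome)))
    return(setNames(Biostrings::width(genome), names(genome)))
  }
  if (is(genome, "Seqinfo")) {
    return(setNames(GenomeInfoDb::seqlengths(genome),
                    GenomeInfoDb::seqnames(genome)))
  }
  if (is.numeric(genome) && !is.null(names(genome))) {
    stopifnot(all(genome > 0))
    return(setNames(as.integer(genome), names(genome)))
  }
  stop("cannot derive chromosome sizes from object of class ",
       paste(class(genome), collapse = "/"))
}

#' Read / write two-column chrom.sizes files
#'
#' @param path file path.
#' @return named integer vector (for the reader).
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  setNames(tab$size, tab$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(chrom = names(sizes), size = as.integer(sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared seqinfo builder
.seqinfo <- function(sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(sizes),
                        seqlengths = as.integer(sizes))
}

# interval midpoint summit, ties to the lower coordinate (0-based midpoint
# floor((start0 + end0 - 1) / 2) expressed on 1-based GRanges coordinates)
.summits <- function(gr) {
  mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(mid, width = 1),
                         strand = GenomicRanges::strand(gr),
                         seqinfo = GenomeInfoDb::seqinfo(gr))
}
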