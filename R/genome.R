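#' @include AllGenerics.R
NULL

#' Construct a GenomeSpec
#'
#' @param lengths numeric(12) chromosome lengths in bp, in id order 1..12.
#' @param centromeres numeric(12) centromere positions in bp.
#' @param geneCounts optional integer(12) genes residing on each chromosome.
#' @param linkCounts optional integer(12) predicted inter-chromosome
#'   functional links of each chromosome.
#' @param windowSize binning window in bp (default 10,000).
#' @return a [GenomeSpec-class].
#' @examples
#' g <- riceGenome()
#' chromLengths(g)[1]
#' @export
GenomeSpec <- function(lengths, centromeres, geneCounts = NA_integer_,
                       linkCounts = NA_integer_, windowSize = 1e4) {
  stopifnot(length(lengths) == 12L, length(centromeres) == 12L)
  ch <- data.frame(
    id = 1:12,
    length = as.numeric(lengths),
    centromere = as.numeric(centromeres),
    relativeSize = as.numeric(lengths) / as.numeric(lengths)[1],
    geneCount = as.integer(rep_len(geneCounts, 12L)),
    linkCount = as.integer(rep_len(linkCounts, 12L)))
  ch$relativeSize[1] <- 1
  new("GenomeSpec", chromosomes = ch, windowSize = as.numeric(windowSize))
}

#' Default rice genome model
#'
#' Twelve chromosomes with lengths and centromere positions approximating
#' the Nipponbare reference assembly; gene and link counts are left NA
#' (they are supplied externally when the factor-correlation analysis is
#' run).
#'
#' @param windowSize binning window in bp.
#' @return a [GenomeSpec-class].
#' @export
riceGenome <- function(windowSize = 1e4) {
  lengths <- c(43270923, 35937250, 36413819, 35502694, 29958434, 31248787,
               29697621, 28443022, 23012720, 23207287, 29021106, 27531856)
  centromeres <- c(16.7e6, 13.6e6, 19.4e6, 9.7e6, 12.4e6, 15.3e6,
                   12.1e6, 12.9e6, 2.8e6, 8.2e6, 12.0e6, 11.9e6)
  GenomeSpec(lengths, centromeres, windowSize = windowSize)
}

chromNames <- function() sprintf("chr%02d", 1:12)

## Normalize assorted chromosome labels ("1", "chr1", "Chr. 01") to 1..12.
chromId <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]\\.?\\s*", "", x)
  id <- suppressWarnings(as.integer(x))
  if (anyNA(id) || any(id < 1L | id > 12L))
    stop("unknown chromosome label(s): ",
         paste(unique(x[is.na(id) | id < 1 | id > 12]), collapse = ", "),
         call. = FALSE)
  id
}

#' Tile a genome into depth windows
#'
#' Windows tile each chromosome at the genome's window size; the final
#' window of a chromosome may be short. The returned \code{GRanges}
#' carries per-window overlap lengths with the short and long arm
#' (windows spanning the centromere are split at the centromere for
#' dosage weighting) and the id of the arm containing the window
#' midpoint.
#'
#' @param genome a [GenomeSpec-class].
#' @return \code{GRanges} with metadata columns \code{sOvl}, \code{lOvl},
#'   \code{arm}.
#' @export
genomeWindows <- function(genome) {
  ch <- genome@chromosomes
  sl <- stats::setNames(ch$length, chromNames())
  gr <- GenomicRanges::tileGenome(sl, tilewidth = genome@windowSize,
                                  cut.last.tile.in.chrom = TRUE)
  cen <- ch$centromere[match(as.character(GenomeInfoDb::seqnames(gr)),
                             chromNames())]
  st <- GenomicRanges::start(gr) - 1  # 0-based
  en <- GenomicRanges::end(gr)
  sOvl <- pmax(0, pmin(en, cen) - st)
  lOvl <- (en - st) - sOvl
  mid <- (st + en) / 2
  S4Vectors::mcols(gr)$sOvl <- sOvl
  S4Vectors::mcols(gr)$lOvl <- lOvl
  S4Vectors::mcols(gr)$arm <- ifelse(mid < cen, "S", "L")
  gr
}

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeSpec", function(x)
  stats::setNames(x@chromosomes$length, chromNames()))

#' @rdname accessors
#' @export
setMethod("centromeres", "GenomeSpec", function(x)
  stats::setNames(x@chromosomes$centromere, chromNames()))

#' @rdname accessors
#' @export
setMethod("relativeSizes", "GenomeSpec", function(x)
  stats::setNames(x@chromosomes$relativeSize, chromNames()))

#' @rdname accessors
#' @export
setMethod("windowSize", "GenomeSpec", function(x) x@windowSize)

#' @rdname accessors
#' @export
setMethod("geneCounts", "GenomeSpec", function(x)
  stats::setNames(x@chromosomes$geneCount, chromNames()))

#' @rdname accessors
#' @export
setMethod("linkCounts", "GenomeSpec", function(x)
  stats::setNames(x@chromosomes$linkCount, chromNames()))

setMethod("show", "GenomeSpec", function(object) {
  ch <- object@chromosomes
  cat("GenomeSpec with", nrow(ch), "chromosomes,",
      sprintf("%.1f Mb total, %g bp windows\n",
              sum(ch$length) / 1e6, object@windowSize))
})
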