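#' @include AllGenerics.R
NULL

#' Read a BED-like binned depth file
#'
#' Four tab-separated columns \code{chrom start end count} with 0-based
#' half-open coordinates; windows are validated to be sorted and
#' non-overlapping within each chromosome.
#'
#' @param path file path.
#' @param genome a [GenomeSpec-class] (arm annotation of the windows).
#' @param id individual label (defaults to the file name).
#' @return a [DepthProfile-class].
#' @export
readBinnedDepth <- function(path, genome,
                            id = sub("\\.[^.]*$", "", basename(path))) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "count"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  bad <- which(is.na(raw$start) | is.na(raw$end) | is.na(raw$count) |
               raw$end <= raw$start | raw$count < 0)
  if (length(bad))
    kError(paste0("malformed window at line ", bad[1], " of ", path),
           "karyoParseError")
  ids <- chromId(raw$chrom)
  cen <- centromeres(genome)[ids]
  for (i in unique(ids)) {
    sel <- ids == i
    st <- raw$start[sel]; en <- raw$end[sel]
    if (is.unsorted(st, strictly = TRUE) || any(st[-1] < en[-sum(sel)]))
      kError(paste("overlapping or out-of-order windows on",
                   chromNames()[i], "in", path), "karyoParseError")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chromNames()[ids],
    ranges = IRanges::IRanges(start = raw$start + 1, end = raw$end))
  sOvl <- pmax(0, pmin(raw$end, cen) - raw$start)
  S4Vectors::mcols(gr)$sOvl <- sOvl
  S4Vectors::mcols(gr)$lOvl <- (raw$end - raw$start) - sOvl
  S4Vectors::mcols(gr)$arm <- ifelse((raw$start + raw$end) / 2 < cen, "S", "L")
  S4Vectors::mcols(gr)$count <- raw$count
  new("DepthProfile", individualId = id, windows = gr,
      totalCount = sum(raw$count))
}

#' Write a depth profile as BED-like TSV
#'
#' Writes \code{chrom start end count} (0-based half-open, no header)
#' plus an optional sidecar JSON of per-chromosome and total counts.
#'
#' @param profile a [DepthProfile-class].
#' @param path output path.
#' @param sidecar also write \code{<path>.totals.json}.
#' @return invisibly, the path.
#' @export
writeBinnedDepth <- function(profile, path, sidecar = TRUE) {
  gr <- profile@windows
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   count = S4Vectors::mcols(gr)$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(individual_id = profile@individualId,
           total_count = profile@totalCount,
           chrom_counts = as.list(chromCounts(profile))),
      paste0(path, ".totals.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an idxstats-style per-chromosome count table
#'
#' Four tab-separated columns \code{chrom length mapped unmapped}; the
#' \code{"*"} row is ignored. Supports whole-chromosome calling only.
#'
#' @param path file path.
#' @return named numeric(12) of mapped read counts.
#' @export
readIdxstats <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length", "mapped",
                                         "unmapped"))
  raw <- raw[raw$chrom != "*", , drop = FALSE]
  ids <- chromId(raw$chrom)
  if (anyDuplicated(ids))
    kError("duplicate chromosome rows in idxstats file", "karyoParseError")
  if (length(ids) != 12L)
    kError("idxstats file must cover all 12 chromosomes", "karyoParseError")
  out <- numeric(12)
  out[ids] <- raw$mapped
  stats::setNames(out, chromNames())
}

#' Write / read a threshold set
#'
#' CSV \code{chrom,gain_threshold,loss_threshold} plus a JSON provenance
#' block at \code{<path>.provenance.json}.
#'
#' @param thresholds a [ThresholdSet-class].
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeThresholds <- function(thresholds, path) {
  utils::write.csv(data.frame(chrom = chromNames(),
                              gain_threshold = thresholds@gain,
                              loss_threshold = thresholds@loss),
                   path, row.names = FALSE)
  jsonlite::write_json(thresholds@provenance,
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  df <- utils::read.csv(path)
  prov <- paste0(path, ".provenance.json")
  provenance <- if (file.exists(prov))
    jsonlite::read_json(prov, simplifyVector = TRUE) else list()
  ord <- chromId(df$chrom)
  gain <- loss <- numeric(12)
  gain[ord] <- df$gain_threshold
  loss[ord] <- df$loss_threshold
  new("ThresholdSet", gain = gain, loss = loss, averageGain = mean(gain),
      averageLoss = mean(loss), provenance = as.list(provenance))
}

#' Write karyotype calls as CSV
#'
#' Columns: individual_id, karyotype_string, category, is_segmental,
#' is_hidden, chromosome_number.
#'
#' @param calls list of [KaryotypeCall-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCalls <- function(calls, path) {
  utils::write.csv(callSummary(calls), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated population's truth table
#'
#' CSV \code{individual_id,karyotype_string,cross_direction}.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTruth <- function(pop, path) {
  utils::write.csv(data.frame(
    individual_id = vapply(pop@profiles, individualId, ""),
    karyotype_string = pop@karyotypeLabels,
    cross_direction = pop@crossDirection), path, row.names = FALSE)
  invisible(path)
}
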