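#' @include AllGenerics.R
NULL

#' Normalized per-chromosome coverage (Key values rescaled by their mean)
#'
#' For chromosome i with summed read count R_i and relative size s_i
#' (chromosome 1 = 1), the Key value is
#' \code{key_i = R_i * 12 / R_total / s_i}; the reported normalized value
#' is \code{key_i / mean(key)}. A proportionally covered euploid profile
#' yields exactly 1 on every chromosome, and the mean of the 12 values is
#' 1 by construction for every profile.
#'
#' @param x a [DepthProfile-class], or a named numeric vector of
#'   per-chromosome read counts (e.g. from [readIdxstats()]).
#' @param genome a [GenomeSpec-class].
#' @return a [NormalizedCoverage-class].
#' @export
normalizedCoverage <- function(x, genome) {
  counts <- if (is(x, "DepthProfile")) chromCounts(x) else {
    out <- stats::setNames(rep(NA_real_, 12), chromNames())
    out[chromNames()[chromId(names(x))]] <- as.numeric(x)
    out
  }
  if (any(is.na(counts)))
    kError("chromosome missing from profile", "karyoValidationError")
  total <- sum(counts)
  if (total <= 0) kError("zero total read count", "karyoValidationError")
  key <- counts * 12 / total / relativeSizes(genome)
  new("NormalizedCoverage", values = as.numeric(key / mean(key)),
      meanDepth = total * READ_LENGTH / sum(chromLengths(genome)))
}

#' @rdname accessors
#' @export
setMethod("coverageValues", "NormalizedCoverage", function(x)
  stats::setNames(x@values, chromNames()))
#' @rdname accessors
#' @export
setMethod("meanDepth", "NormalizedCoverage", function(x) x@meanDepth)

setMethod("show", "NormalizedCoverage", function(object) {
  cat("NormalizedCoverage (mean depth",
      sprintf("%.3fx):\n", object@meanDepth))
  print(round(stats::setNames(object@values, chromNames()), 4))
})

#' Closed-form expected normalized value for a dosage change
#'
#' Expected normalized coverage of a chromosome whose dosage deviates by
#' \code{delta} copies from the tetraploid baseline while the other 11
#' chromosomes stay euploid, under exact proportional sampling:
#' \code{(1 + delta/4) * 12 / (12 + delta/4)}. delta = +1 gives 60/49,
#' delta = -1 gives 36/47.
#'
#' @param delta integer copy deviation(s), -4..+4.
#' @return numeric expected value(s).
#' @export
expectedThreshold <- function(delta) {
  if (any(delta < -4 | delta > 4))
    kError("delta must lie in -4..+4", "karyoValidationError")
  (1 + delta / 4) * 12 / (12 + delta / 4)
}

#' Derive gain/loss calling thresholds by simulation
#'
#' For each chromosome and direction, a single-chromosome gain (+1) or
#' loss (-1) karyotype is simulated at the configured depth and its
#' normalized coverage on the altered chromosome recorded, averaged over
#' \code{nReps} replicates. Averaging the 12 per-chromosome thresholds
#' per direction yields the two average thresholds. With noise "none"
#' every gain threshold equals 60/49 and every loss threshold 36/47
#' exactly.
#'
#' @param genome a [GenomeSpec-class].
#' @param cfg a [SimConfig-class]; its seed makes the derivation
#'   deterministic.
#' @param nReps simulation replicates per threshold (default 3).
#' @return a [ThresholdSet-class].
#' @export
deriveThresholds <- function(genome, cfg, nReps = 3L) {
  if (nReps < 1L) kError("nReps must be >= 1", "karyoValidationError")
  windows <- genomeWindows(genome)
  seeds <- matrix(subSeeds(cfg@seed, 24L * nReps), nrow = nReps)
  gain <- loss <- numeric(12)
  col <- 0L
  for (dir in c(1L, -1L)) {
    for (i in 1:12) {
      col <- col + 1L
      k <- Karyotype(whole = stats::setNames(dir, i))
      vals <- vapply(seq_len(nReps), function(r) {
        ci <- cfg
        ci@seed <- seeds[r, col]
        p <- simulateProfile(k, ci, windows = windows)
        normalizedCoverage(p, genome)@values[i]
      }, numeric(1))
      if (dir > 0) gain[i] <- mean(vals) else loss[i] <- mean(vals)
    }
  }
  new("ThresholdSet", gain = gain, loss = loss, averageGain = mean(gain),
      averageLoss = mean(loss),
      provenance = list(nReps = as.integer(nReps), meanDepth = cfg@meanDepth,
                        noise = cfg@noise, seed = cfg@seed))
}

#' Closed-form threshold set
#'
#' The noise-free limit of [deriveThresholds()]: gain 60/49 and loss
#' 36/47 on every chromosome.
#'
#' @return a [ThresholdSet-class].
#' @export
closedFormThresholds <- function() {
  new("ThresholdSet", gain = rep(expectedThreshold(1L), 12),
      loss = rep(expectedThreshold(-1L), 12),
      averageGain = expectedThreshold(1L),
      averageLoss = expectedThreshold(-1L),
      provenance = list(nReps = 0L, meanDepth = Inf, noise = "none",
                        seed = NA_integer_))
}

#' @rdname accessors
#' @export
setMethod("gainThresholds", "ThresholdSet", function(x)
  stats::setNames(x@gain, chromNames()))
#' @rdname accessors
#' @export
setMethod("lossThresholds", "ThresholdSet", function(x)
  stats::setNames(x@loss, chromNames()))

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet: average gain %.4f, average loss %.4f (%s, %gx, %d reps)\n",
              object@averageGain, object@averageLoss,
              object@provenance$noise, object@provenance$meanDepth,
              object@provenance$nReps))
})
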