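#' @import methods
#' @importFrom S4Vectors mcols
#' @importClassesFrom GenomicRanges GRanges
NULL

N_CHROM <- 12L
BASELINE_DOSAGE <- 4L

#' GenomeSpec: the 12-chromosome genome model
#'
#' Holds per-chromosome lengths, centromere positions, relative sizes
#' (chromosome 1 == 1), optional gene and inter-chromosome functional-link
#' counts, and the binning window size used for depth profiles.
#'
#' @slot chromosomes data.frame with columns \code{id}, \code{length},
#'   \code{centromere}, \code{relativeSize}, \code{geneCount},
#'   \code{linkCount}; exactly 12 rows with ids 1..12.
#' @slot windowSize binning window in bp (default 10,000).
#' @export
setClass("GenomeSpec",
  representation(chromosomes = "data.frame", windowSize = "numeric"))

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  msg <- character()
  need <- c("id", "length", "centromere", "relativeSize",
            "geneCount", "linkCount")
  if (!all(need %in% names(ch)))
    return(paste("chromosomes must have columns:", paste(need, collapse = ", ")))
  if (nrow(ch) != N_CHROM || !identical(sort(as.integer(ch$id)), 1:12))
    msg <- c(msg, "exactly 12 chromosomes with distinct ids 1..12 required")
  if (any(ch$length <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (any(ch$centromere <= 0 | ch$centromere >= ch$length))
    msg <- c(msg, "centromere must lie strictly inside the chromosome")
  i1 <- which(ch$id == 1L)
  if (length(i1) == 1L) {
    if (ch$relativeSize[i1] != 1)
      msg <- c(msg, "relativeSize of chromosome 1 must be exactly 1")
    if (any(abs(ch$relativeSize - ch$length / ch$length[i1]) > 1e-9))
      msg <- c(msg, "relativeSize must equal length / length(chr1)")
  }
  if (length(object@windowSize) != 1L || object@windowSize <= 0)
    msg <- c(msg, "windowSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Karyotype: dosage deviations from the tetraploid baseline
#'
#' Copy-number deviations per chromosome relative to the euploid
#' tetraploid baseline of 4: whole-chromosome deltas plus short-arm (S)
#' and long-arm (L) deltas for segmental aneuploidy.
#'
#' @slot whole integer(12), whole-chromosome copy deviation (-4..+4).
#' @slot shortArm integer(12), extra deviation of the short arm.
#' @slot longArm integer(12), extra deviation of the long arm.
#' @export
setClass("Karyotype",
  representation(whole = "integer", shortArm = "integer", longArm = "integer"),
  prototype(whole = integer(12), shortArm = integer(12), longArm = integer(12)))

setValidity("Karyotype", function(object) {
  msg <- character()
  if (length(object@whole) != N_CHROM || length(object@shortArm) != N_CHROM ||
      length(object@longArm) != N_CHROM)
    return("whole, shortArm and longArm must each have length 12")
  if (anyNA(object@whole) || anyNA(object@shortArm) || anyNA(object@longArm))
    msg <- c(msg, "deltas must not be NA")
  else {
    if (any(abs(object@whole) > 4))
      msg <- c(msg, "whole-chromosome deltas must lie in -4..+4")
    if (any(BASELINE_DOSAGE + object@whole + object@shortArm < 0) ||
        any(BASELINE_DOSAGE + object@whole + object@longArm < 0))
      msg <- c(msg, "dosage of an arm region cannot go below 0")
  }
  if (length(msg)) msg else TRUE
})

#' KaryotypeClass: classification of a karyotype
#'
#' @slot category one of "euploid", "simple_gain", "simple_loss", "compound".
#' @slot isSegmental TRUE if any arm-level delta is nonzero.
#' @slot isHidden TRUE for balanced (48-chromosome) compound aneuploids.
#' @slot chromosomeNumber somatic chromosome number (48 + net whole-chromosome
#'   change), or NA when arm-level terms make it undefined.
#' @export
setClass("KaryotypeClass",
  representation(category = "character", isSegmental = "logical",
                 isHidden = "logical", chromosomeNumber = "integer"))

setValidity("KaryotypeClass", function(object) {
  ok <- c("euploid", "simple_gain", "simple_loss", "compound")
  if (!(length(object@category) == 1L && object@category %in% ok))
    return(paste("category must be one of:", paste(ok, collapse = ", ")))
  if (isTRUE(object@isHidden) && object@category != "compound")
    return("hidden aneuploidy implies compound category")
  TRUE
})

#' SimConfig: configuration of the count-level coverage simulator
#'
#' @slot genome a [GenomeSpec-class].
#' @slot meanDepth target mean fold-coverage of the haploid reference
#'   (1.0 mirrors the 1x simulation regime used to derive thresholds).
#' @slot noise "multinomial" (total read count conserved), "poisson"
#'   (independent window counts with matching means), or "none"
#'   (exact expected counts, for closed-form checks).
#' @slot mappabilitySd sd of a per-window log-normal weight multiplier
#'   (0 = uniform mappability).
#' @slot seed integer master seed, or NA for the current RNG state.
#' @export
setClass("SimConfig",
  representation(genome = "GenomeSpec", meanDepth = "numeric",
                 noise = "character", mappabilitySd = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@meanDepth) != 1L || object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be a single positive number")
  if (!(object@noise %in% c("multinomial", "poisson", "none")))
    msg <- c(msg, "noise must be 'multinomial', 'poisson' or 'none'")
  if (length(object@mappabilitySd) != 1L || object@mappabilitySd < 0)
    msg <- c(msg, "mappabilitySd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DepthProfile: binned read counts for one individual
#'
#' Window-level read counts across the 12 chromosomes, tiled at the
#' genome's window size (final window of a chromosome may be short).
#'
#' @slot individualId sample label.
#' @slot windows a \code{GRanges} tiling the genome, with a \code{count}
#'   metadata column (non-negative; fractional under the "none" noise model).
#' @slot totalCount sum of all window counts.
#' @export
setClass("DepthProfile",
  representation(individualId = "character", windows = "GRanges",
                 totalCount = "numeric"))

setValidity("DepthProfile", function(object) {
  cnt <- S4Vectors::mcols(object@windows)$count
  if (is.null(cnt))
    return("windows must carry a 'count' metadata column")
  if (any(cnt < 0))
    return("window counts must be non-negative")
  if (abs(object@totalCount - sum(cnt)) > 1e-6 * max(1, sum(cnt)))
    return("totalCount must equal the sum of window counts")
  TRUE
})

#' NormalizedCoverage: per-chromosome Key values rescaled by their mean
#'
#' The normalized-coverage statistic: for chromosome i with summed read
#' count R_i and relative size s_i, key_i = R_i * 12 / R_total / s_i, and
#' the reported value is key_i / mean(key). A proportionally covered
#' euploid gives 1 on every chromosome.
#'
#' @slot values numeric(12) normalized coverage per chromosome.
#' @slot meanDepth the individual's mean raw fold-coverage
#'   (total reads x read length / genome length).
#' @export
setClass("NormalizedCoverage",
  representation(values = "numeric", meanDepth = "numeric"))

setValidity("NormalizedCoverage", function(object) {
  if (length(object@values) != N_CHROM)
    return("values must have length 12")
  if (any(object@values < 0)) return("values must be non-negative")
  TRUE
})

#' ThresholdSet: simulation-derived gain and loss calling thresholds
#'
#' @slot gain numeric(12) per-chromosome gain thresholds (> 1).
#' @slot loss numeric(12) per-chromosome loss thresholds (< 1).
#' @slot averageGain mean of the 12 gain thresholds.
#' @slot averageLoss mean of the 12 loss thresholds.
#' @slot provenance list (nReps, meanDepth, noise, seed).
#' @export
setClass("ThresholdSet",
  representation(gain = "numeric", loss = "numeric", averageGain = "numeric",
                 averageLoss = "numeric", provenance = "list"))

setValidity("ThresholdSet", function(object) {
  if (length(object@gain) != N_CHROM || length(object@loss) != N_CHROM)
    return("gain and loss must each have length 12")
  if (!all(object@loss < 1) || !all(object@gain > 1))
    return("every chromosome must satisfy loss threshold < 1 < gain threshold")
  TRUE
})

#' KaryotypeCall: the caller's verdict for one individual
#'
#' @slot individualId sample label.
#' @slot karyotype the called [Karyotype-class].
#' @slot wholeValues numeric(12) normalized coverage values (baseline-refined
#'   scale) used for the whole-chromosome calls.
#' @slot armValues 12 x 2 matrix (columns S, L) of arm-level values.
#' @slot events data.frame of called events: chrom, arm ("", "S", "L"),
#'   delta, value, consistency (fraction of supporting windows; NA for
#'   whole-chromosome events only when windows are unavailable).
#' @slot classification the [KaryotypeClass-class] of the called karyotype.
#' @slot notes character vector of caller warnings (downgrades, short arms).
#' @export
setClass("KaryotypeCall",
  representation(individualId = "character", karyotype = "Karyotype",
                 wholeValues = "numeric", armValues = "matrix",
                 events = "data.frame", classification = "KaryotypeClass",
                 notes = "character"))

#' TraitEffectModel: generative model for aneuploidy trait effects
#'
#' General effects shift every aneuploid individual on a subset of traits;
#' specific effects shift only carriers of a particular karyotype.
#'
#' @slot traitNames character(nTraits).
#' @slot baseline numeric(nTraits) euploid trait means.
#' @slot generalEffect numeric(nTraits) mean shift applied to every
#'   aneuploid individual (default: -1 on the first 12 of 21 traits).
#' @slot specificEffects data.frame(karyotype, trait, shift): extra shift
#'   for carriers of the canonical karyotype string.
#' @slot noiseSd numeric(nTraits) Gaussian residual sd per trait.
#' @export
setClass("TraitEffectModel",
  representation(traitNames = "character", baseline = "numeric",
                 generalEffect = "numeric", specificEffects = "data.frame",
                 noiseSd = "numeric"))

setValidity("TraitEffectModel", function(object) {
  n <- length(object@traitNames)
  if (length(object@baseline) != n || length(object@generalEffect) != n ||
      length(object@noiseSd) != n)
    return("baseline, generalEffect and noiseSd must match traitNames length")
  if (any(object@noiseSd < 0)) return("noiseSd must be >= 0")
  se <- object@specificEffects
  if (nrow(se)) {
    if (!all(c("karyotype", "trait", "shift") %in% names(se)))
      return("specificEffects needs columns karyotype, trait, shift")
    tr <- se$trait
    if (is.numeric(tr) && any(tr < 1 | tr > n))
      return("specificEffects trait index out of range")
    if (is.character(tr) && !all(tr %in% object@traitNames))
      return("specificEffects trait name not in traitNames")
  }
  TRUE
})

#' SimulatedPopulation: simulated profiles with ground truth
#'
#' @slot profiles list of [DepthProfile-class].
#' @slot truth list of true [Karyotype-class] objects, parallel to profiles.
#' @slot karyotypeLabels canonical karyotype strings, parallel to profiles.
#' @slot traits numeric matrix individuals x traits, or NULL.
#' @slot crossDirection character ("NN99"/"99NN") per individual.
#' @slot genome the [GenomeSpec-class] used.
#' @export
setClass("SimulatedPopulation",
  representation(profiles = "list", truth = "list",
                 karyotypeLabels = "character", traits = "ANY",
                 crossDirection = "character", genome = "GenomeSpec"))

setValidity("SimulatedPopulation", function(object) {
  n <- length(object@profiles)
  if (length(object@truth) != n)
    return("every simulated individual must have a true karyotype")
  if (length(object@karyotypeLabels) != n)
    return("karyotypeLabels must parallel profiles")
  if (length(object@crossDirection) != n)
    return("crossDirection must parallel profiles")
  if (!is.null(object@traits) && nrow(object@traits) != n)
    return("traits matrix must have one row per individual")
  TRUE
})
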